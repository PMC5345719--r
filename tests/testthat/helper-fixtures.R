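# Shared fixtures and independent oracles. The oracles are deliberately
# naive explicit scans over the input string, written without rle(), so they
# share no code path with the package implementation.

# --- naive single-row oracles for the three ABH passes ---------------------

oracle_impute <- function(x) {
  n <- length(x)
  out <- x
  i <- 1
  while (i <= n) {
    if (x[i] == "N") {
      j <- i
      while (j <= n && x[j] == "N") j <- j + 1
      if (i > 1 && j <= n && x[i - 1] == x[j]) out[i:(j - 1)] <- x[i - 1]
      i <- j
    } else i <- i + 1
  }
  out
}

oracle_het <- function(x, hmax = 4) {
  n <- length(x)
  out <- x
  i <- 1
  while (i <= n) {
    if (x[i] != "H") {
      j <- i
      while (j <= n && x[j] != "H") j <- j + 1
      if (i > 1 && j <= n && (j - i) <= hmax) out[i:(j - 1)] <- "H"
      i <- j
    } else i <- i + 1
  }
  out
}

oracle_stretch <- function(x, smax = 1) {
  n <- length(x)
  out <- x
  i <- 1
  while (i <= n) {
    j <- i
    while (j <= n && x[j] == x[i]) j <- j + 1
    if (i > 1 && j <= n && (j - i) <= smax && x[i - 1] == x[j] &&
        x[i - 1] != "N")
      out[i:(j - 1)] <- x[i - 1]
    i <- j
  }
  out
}

# --- ABH fixture builders ---------------------------------------------------

# one or more genotype strings ("AANAH...") -> ABHMatrix on one chromosome
abh_from_strings <- function(strs, chrom = NULL, pos = NULL) {
  rows <- strsplit(strs, "")
  L <- length(rows[[1]])
  codes <- do.call(rbind, rows)
  rownames(codes) <- paste0("ind", seq_along(strs))
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- stats::ave(seq_len(L), chrom, FUN = seq_along)
  ABHMatrix(codes, data.frame(id = paste0("m", seq_len(L)), chrom = chrom,
                              pos = pos, stringsAsFactors = FALSE))
}

abh_string <- function(g, ind = 1) paste(abhCodes(g)[ind, ], collapse = "")

# apply a single-row oracle to every row, preserving matrix shape at L = 1
oracle_rows <- function(rows, fn, ...) {
  do.call(rbind, lapply(seq_len(nrow(rows)), function(i) fn(rows[i, ], ...)))
}

# all strings over {A,B,H,N} of length L, one per row
all_abh_strings <- function(L) {
  as.matrix(do.call(expand.grid,
                    c(rep(list(c("A", "B", "H", "N")), L),
                      stringsAsFactors = FALSE)))
}

# --- SiteMatrix fixture builder --------------------------------------------

# calls: character matrix sites x samples, entries like "GG", "GT", or NA
site_fixture <- function(calls, roles, chrom = NULL, pos = NULL,
                         ref = "G", alt = "T", dref = NULL, dalt = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100
  g1 <- matrix(NA_character_, n, ncol(calls))
  g2 <- matrix(NA_character_, n, ncol(calls))
  for (i in seq_len(n)) for (j in seq_len(ncol(calls))) {
    tok <- calls[i, j]
    if (!is.na(tok)) {
      ab <- sort(c(substr(tok, 1, 1), substr(tok, 2, 2)))
      g1[i, j] <- ab[1]; g2[i, j] <- ab[2]
    }
  }
  markers <- data.frame(id = paste0("s", seq_len(n)), chrom = chrom,
                        pos = pos, ref = rep(ref, n)[seq_len(n)],
                        alt = rep(alt, n)[seq_len(n)],
                        stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("smp", seq_len(ncol(calls))),
                        role = roles, stringsAsFactors = FALSE)
  SiteMatrix(markers, samples, g1, g2, dref, dalt)
}

# --- small on-disk format fixtures -----------------------------------------

write_test_hapmap <- function(path) {
  meta <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  lines <- c(
    paste(c(meta, "P1a", "P2a", "F2_1", "F2_2"), collapse = "\t"),
    paste(c("s1", "G/T", "1", "1000", "+", "x", "x", "x", "x", "x", "x",
            "G", "T", "K", "GG"), collapse = "\t"),
    paste(c("s2", "A/C", "1", "2000", "+", "x", "x", "x", "x", "x", "x",
            "A", "C", "N", "AC"), collapse = "\t"),
    paste(c("s3", "C/T", "2", "500", "+", "x", "x", "x", "x", "x", "x",
            "C", "T", "TT", "Y"), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "1000", "v1", "G", "T", ".", "PASS", ".", "GT:AD",
            "0/1:6,5", "0/0:9,0"), collapse = "\t"),
    paste(c("1", "2000", "v2", "A", "C", ".", "PASS", ".", "GT:AD",
            "1/1:0,8", "./.:0,0"), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_test_roles <- function(path, ids, roles) {
  writeLines(paste(ids, roles, sep = "\t"), path)
  path
}

# simulate two linked F2 marker columns at recombination fraction r
sim_linked_pair <- function(n, r) {
  g1a <- stats::rbinom(n, 1, 0.5); g1b <- stats::rbinom(n, 1, 0.5)
  g2a <- ifelse(stats::runif(n) < r, 1 - g1a, g1a)
  g2b <- ifelse(stats::runif(n) < r, 1 - g1b, g1b)
  list(x = c("A", "H", "B")[g1a + g1b + 1],
       y = c("A", "H", "B")[g2a + g2b + 1])
}

# independent grid-search likelihood oracle for the two-point F2 estimate
oracle_rf_grid <- function(x, y, step = 1e-4) {
  ok <- x != "N" & y != "N"
  xi <- match(x[ok], c("A", "H", "B"))
  yi <- match(y[ok], c("A", "H", "B"))
  grid <- seq(1e-6, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    s <- 1 - r
    P <- matrix(c(s^2 / 4, r * s / 2, r^2 / 4,
                  r * s / 2, (s^2 + r^2) / 2, r * s / 2,
                  r^2 / 4, r * s / 2, s^2 / 4), 3, 3, byrow = TRUE)
    sum(log(P[cbind(xi, yi)]))
  }, numeric(1))
  grid[which.max(ll)]
}
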