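# Readers and writers: TASSEL-style HapMap text, VCF 4.2 (GT + AD), the
# ABH-CSV dialect, and the two-column sample-roles table. All coordinates
# are 1-based inclusive.

IUPAC_HET <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Construct a SiteMatrix
#'
#' Sorts markers by (chromosome, position), aligns all matrices, and
#' validates invariants (unique positions, consistent dimensions, unordered
#' allele pairs).
#'
#' @param markers data.frame with columns id, chrom, pos, ref, alt.
#' @param samples data.frame with columns id, role (parent1_rep,
#'   parent2_rep or f2).
#' @param geno1,geno2 character matrices, sites x samples; NA = missing.
#' @param depthRef,depthAlt integer matrices of per-allele read depths;
#'   default all zero.
#' @param filterLog optional audit-trail data.frame.
#' @return a \linkS4class{SiteMatrix}
#' @export
SiteMatrix <- function(markers, samples, geno1, geno2,
                       depthRef = NULL, depthAlt = NULL, filterLog = NULL) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(depthRef))
    depthRef <- matrix(0L, nrow(markers), nrow(samples))
  if (is.null(depthAlt))
    depthAlt <- matrix(0L, nrow(markers), nrow(samples))
  if (is.null(filterLog))
    filterLog <- data.frame(stage = character(0), sites_in = integer(0),
                            sites_out = integer(0), calls_masked = integer(0),
                            params = character(0), stringsAsFactors = FALSE)
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  if (!"parentA" %in% names(markers)) markers$parentA <- NA_character_
  if (!"parentB" %in% names(markers)) markers$parentB <- NA_character_
  fix <- function(m) {
    m <- m[o, , drop = FALSE]
    dimnames(m) <- list(markers$id, samples$id)
    m
  }
  new("SiteMatrix", markers = markers, samples = samples,
      geno1 = fix(geno1), geno2 = fix(geno2),
      depthRef = fix(depthRef), depthAlt = fix(depthAlt),
      filterLog = filterLog)
}

#' Construct an ABHMatrix
#'
#' @param codes character matrix, individuals x markers, entries A/B/H/N.
#' @param markers data.frame with columns id, chrom, pos.
#' @param units "bp" (physical) or "cM" (genetic) positions.
#' @return an \linkS4class{ABHMatrix}
#' @export
ABHMatrix <- function(codes, markers, units = "bp") {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  codes <- codes[, o, drop = FALSE]
  colnames(codes) <- markers$id
  new("ABHMatrix", codes = codes, markers = markers, units = units)
}

#' Read a sample-roles table
#'
#' Two-column whitespace- or tab-separated text mapping sample id to role
#' (\code{parent1_rep}, \code{parent2_rep}, \code{f2}); a header line
#' \code{id<TAB>role} is allowed and skipped.
#'
#' @param path file path
#' @return data.frame with columns id, role
#' @export
readRoles <- function(path) {
  tb <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "role"))
  if (nrow(tb) && tolower(tb$id[1]) == "id" && tolower(tb$role[1]) == "role")
    tb <- tb[-1, , drop = FALSE]
  bad <- setdiff(tb$role, c("parent1_rep", "parent2_rep", "f2"))
  if (length(bad))
    stop("unknown role(s) in roles table: ", paste(bad, collapse = ", "))
  rownames(tb) <- NULL
  tb
}

# one genotype token -> c(allele1, allele2) or c(NA, NA)
.parseGenoToken <- function(tok) {
  tok <- toupper(tok)
  if (tok %in% c("N", "NN", "./.", ".", "--", "-")) return(c(NA, NA))
  if (nchar(tok) == 1) {
    if (tok %in% c("A", "C", "G", "T")) return(c(tok, tok))
    if (tok %in% names(IUPAC_HET)) return(IUPAC_HET[[tok]])
    return(c(NA, NA))
  }
  if (nchar(tok) == 2) {
    a <- substr(tok, 1, 1); b <- substr(tok, 2, 2)
    if (all(c(a, b) %in% c("A", "C", "G", "T"))) return(sort(c(a, b)))
    return(c(NA, NA))
  }
  if (grepl("^[ACGT][/|][ACGT]$", tok))
    return(sort(c(substr(tok, 1, 1), substr(tok, 3, 3))))
  c(NA, NA)
}

#' Read a genotype-call table into a SiteMatrix
#'
#' Supported formats: TASSEL-style HapMap text (11 metadata columns then one
#' column per sample; genotypes as single IUPAC codes or allele pairs) and
#' VCF v4.2 with GT and, when present, AD per-sample fields. Sample roles
#' come from a sidecar roles table (see \code{\link{readRoles}}).
#'
#' @param path genotype file
#' @param format "hapmap" or "vcf"
#' @param roles roles data.frame or path to a roles file
#' @return a \linkS4class{SiteMatrix} sorted by (chromosome, position)
#' @export
readSiteMatrix <- function(path, format = c("hapmap", "vcf"), roles) {
  format <- match.arg(format)
  if (is.character(roles)) roles <- readRoles(roles)
  m <- switch(format,
              hapmap = .readHapmap(path),
              vcf = .readVCF(path))
  unknown <- setdiff(roles$id, m$samples$id)
  if (length(unknown))
    stop("roles table names unknown sample(s): ",
         paste(unknown, collapse = ", "))
  missing_role <- setdiff(m$samples$id, roles$id)
  if (length(missing_role))
    stop("samples without a role: ", paste(missing_role, collapse = ", "))
  m$samples$role <- roles$role[match(m$samples$id, roles$id)]
  SiteMatrix(m$markers, m$samples, m$geno1, m$geno2, m$depthRef, m$depthAlt)
}

.readHapmap <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty HapMap file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 12)
    stop("malformed HapMap header (need 11 metadata columns + samples): line 1")
  sample_ids <- hdr[-(1:11)]
  n <- length(lines) - 1
  markers <- data.frame(id = character(n), chrom = character(n),
                        pos = integer(n), ref = NA_character_,
                        alt = NA_character_, stringsAsFactors = FALSE)
  g1 <- matrix(NA_character_, n, length(sample_ids))
  g2 <- matrix(NA_character_, n, length(sample_ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed HapMap record: line ", i + 1)
    markers$id[i] <- f[1]
    markers$chrom[i] <- f[3]
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos)) stop("non-integer position: line ", i + 1)
    markers$pos[i] <- pos
    al <- strsplit(f[2], "/", fixed = TRUE)[[1]]
    if (length(al) >= 1) markers$ref[i] <- toupper(al[1])
    if (length(al) >= 2) markers$alt[i] <- toupper(al[2])
    for (j in seq_along(sample_ids)) {
      ab <- .parseGenoToken(f[11 + j])
      g1[i, j] <- ab[1]; g2[i, j] <- ab[2]
    }
  }
  list(markers = markers,
       samples = data.frame(id = sample_ids, role = "f2",
                            stringsAsFactors = FALSE),
       geno1 = g1, geno2 = g2,
       depthRef = matrix(0L, n, length(sample_ids)),
       depthAlt = matrix(0L, n, length(sample_ids)))
}

.readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(vcfR::getFIX(v)),
               dimnames = dimnames(vcfR::getFIX(v)))
  n <- nrow(fx)
  ids <- fx[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fx[, "CHROM"], "_", fx[, "POS"])[is.na(ids) | ids == "."]
  markers <- data.frame(id = ids, chrom = fx[, "CHROM"],
                        pos = as.integer(fx[, "POS"]),
                        ref = toupper(fx[, "REF"]),
                        alt = toupper(fx[, "ALT"]),
                        stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  sample_ids <- colnames(gt)
  g1 <- matrix(NA_character_, n, length(sample_ids))
  g2 <- matrix(NA_character_, n, length(sample_ids))
  dR <- matrix(0L, n, length(sample_ids))
  dA <- matrix(0L, n, length(sample_ids))
  for (i in seq_len(n)) {
    alleles <- c(markers$ref[i], strsplit(markers$alt[i], ",")[[1]])
    for (j in seq_along(sample_ids)) {
      tok <- gt[i, j]
      if (!is.na(tok) && tok != "." && !grepl("\\.", tok)) {
        idx <- as.integer(strsplit(tok, "[/|]")[[1]]) + 1L
        if (length(idx) == 2 && all(idx >= 1 & idx <= length(alleles))) {
          ab <- sort(alleles[idx])
          g1[i, j] <- ab[1]; g2[i, j] <- ab[2]
        }
      }
      if (!is.null(ad) && !is.na(ad[i, j])) {
        dd <- suppressWarnings(as.integer(strsplit(ad[i, j], ",")[[1]]))
        if (length(dd) >= 1 && !is.na(dd[1])) dR[i, j] <- dd[1]
        if (length(dd) >= 2 && !is.na(dd[2])) dA[i, j] <- dd[2]
      }
    }
  }
  # keep only the first ALT allele as the site's alternate
  markers$alt <- vapply(strsplit(markers$alt, ","), `[`, character(1), 1)
  list(markers = markers,
       samples = data.frame(id = sample_ids, role = "f2",
                            stringsAsFactors = FALSE),
       geno1 = g1, geno2 = g2, depthRef = dR, depthAlt = dA)
}

#' Write a SiteMatrix as minimal VCF 4.2 text
#'
#' Emits GT:AD per sample; missing calls are "./.". Coordinates are 1-based
#' inclusive, stated in the header.
#'
#' @param m a SiteMatrix
#' @param path output file
#' @return invisibly, the path
#' @export
writeSiteVCF <- function(m, path) {
  stopifnot(is(m, "SiteMatrix"))
  mk <- m@markers
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gbsf2 (coordinates 1-based inclusive)",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m@samples$id), collapse = "\t"))
  rows <- vapply(seq_len(nrow(mk)), function(i) {
    alleles <- c(mk$ref[i], mk$alt[i])
    cells <- vapply(seq_len(nrow(m@samples)), function(j) {
      a1 <- m@geno1[i, j]; a2 <- m@geno2[i, j]
      gt <- if (is.na(a1)) "./." else {
        i1 <- match(a1, alleles) - 1L
        i2 <- match(a2, alleles) - 1L
        if (is.na(i1) || is.na(i2)) "./." else paste0(i1, "/", i2)
      }
      paste0(gt, ":", m@depthRef[i, j], ",", m@depthAlt[i, j])
    }, character(1))
    paste(c(mk$chrom[i], mk$pos[i], mk$id[i], mk$ref[i], mk$alt[i],
            ".", "PASS", ".", "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ABH-CSV file
#'
#' Dialect: optional comment line 0 \code{# units=cM}; line 1 =
#' \code{id,<marker ids>}; line 2 = \code{chrom,<chromosome labels>}; line 3
#' = \code{pos,<integer bp or cM>}; each further line = individual id then
#' one of A/B/H/N per marker ("-" is accepted as N on input). Comma
#' separated, no quoting, LF line endings.
#'
#' @param path file path
#' @return an \linkS4class{ABHMatrix}
#' @export
readABHMatrix <- function(path) {
  lines <- readLines(path)
  units <- "bp"
  if (length(lines) && grepl("^#", lines[1])) {
    if (grepl("units=cM", lines[1])) units <- "cM"
    lines <- lines[-1]
  }
  if (length(lines) < 3) stop("ABH-CSV needs id, chrom and pos header lines")
  sp <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(sp[[1]])
  if (sp[[1]][1] != "id" || sp[[2]][1] != "chrom" || sp[[3]][1] != "pos")
    stop("ABH-CSV header lines must start with id, chrom, pos")
  for (k in seq_along(sp))
    if (length(sp[[k]]) != ncols)
      stop("column-count mismatch at line ", k,
           " (expected ", ncols, ", got ", length(sp[[k]]), ")")
  markers <- data.frame(id = sp[[1]][-1], chrom = sp[[2]][-1],
                        pos = as.numeric(sp[[3]][-1]),
                        stringsAsFactors = FALSE)
  body <- sp[-(1:3)]
  codes <- matrix(NA_character_, length(body), ncols - 1)
  inds <- character(length(body))
  for (k in seq_along(body)) {
    inds[k] <- body[[k]][1]
    cell <- body[[k]][-1]
    cell[cell == "-"] <- "N"
    bad <- which(!cell %in% ABH_CODES)
    if (length(bad))
      stop("invalid ABH code '", cell[bad[1]], "' at data row ", k,
           ", column ", bad[1] + 1)
    codes[k, ] <- cell
  }
  rownames(codes) <- inds
  ABHMatrix(codes, markers, units = units)
}

#' Write an ABHMatrix as ABH-CSV
#'
#' Inverse of \code{\link{readABHMatrix}}; \code{write} then \code{read} is
#' the identity on valid matrices. The missing token on output is N.
#'
#' @param x an ABHMatrix
#' @param path output file
#' @return invisibly, the path
#' @export
writeABHMatrix <- function(x, path) {
  stopifnot(is(x, "ABHMatrix"))
  mk <- x@markers
  pos <- if (x@units == "bp") format(as.integer(mk$pos), scientific = FALSE,
                                     trim = TRUE) else as.character(mk$pos)
  lines <- c(
    if (x@units == "cM") "# units=cM" else NULL,
    paste(c("id", mk$id), collapse = ","),
    paste(c("chrom", mk$chrom), collapse = ","),
    paste(c("pos", pos), collapse = ","),
    vapply(seq_len(nrow(x@codes)), function(i) {
      paste(c(rownames(x@codes)[i], x@codes[i, ]), collapse = ",")
    }, character(1))
  )
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header \code{id,trait}, one row per individual.
#'
#' @param path file path
#' @return named numeric vector of trait values
#' @export
readPhenotype <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "trait") %in% names(tb)))
    stop("phenotype CSV must have columns id, trait")
  stats::setNames(as.numeric(tb$trait), tb$id)
}

#' Write a phenotype table
#' @param phen named numeric vector
#' @param path output file
#' @return invisibly, the path
#' @export
writePhenotype <- function(phen, path) {
  utils::write.csv(data.frame(id = names(phen), trait = unname(phen)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genetic map as TSV (chromosome, marker, cM)
#' @param map a GeneticMap
#' @param path output file
#' @return invisibly, the path
#' @export
writeMapTSV <- function(map, path) {
  tb <- mapTable(map)
  utils::write.table(tb[, c("chrom", "marker", "cM")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genetic map from TSV (chromosome, marker, cM)
#' @param path file path
#' @return a \linkS4class{GeneticMap}
#' @export
readMapTSV <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new("GeneticMap",
      table = data.frame(marker = as.character(tb$marker), chrom = tb$chrom,
                         cM = tb$cM, stringsAsFactors = FALSE))
}
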