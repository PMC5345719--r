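# End-to-end orchestration: filter -> encode -> impute -> correct ->
# [merge] -> map -> scan, with per-stage outputs and a machine-readable
# provenance record. Any prefix of stages is runnable via the stage toggles.

.defaultPipelineConfig <- function() {
  list(
    input = NULL,                # genotype file (hapmap or vcf)
    format = "hapmap",
    roles = NULL,                # roles file
    input2 = NULL, format2 = NULL, roles2 = NULL,  # optional second population
    phenotype = NULL,            # phenotype CSV
    out_dir = ".",
    seed = 1,
    stages = list(filter = TRUE, encode = TRUE, impute = TRUE,
                  correct = TRUE, merge = FALSE, map = TRUE, scan = FALSE),
    filter = list(maf = 0.25, min_depth = 7, thin_bp = 64, max_missing = 0.75),
    correct = list(het_run_max = 4, stretch_run_max = 1),
    map = list(map_function = "haldane"),
    scan = list(step_cm = 1, n_draws = 16, n_perm = 1000, alpha = 0.05,
                prob = 0.95)
  )
}

.mergeConfig <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(base[[k]]) && !is.null(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]], paste0(path, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' Starts from full defaults and overlays user settings (a list or a YAML
#' file path); unknown keys are rejected before any stage runs.
#'
#' @param config list or YAML file path; NULL gives the full defaults
#' @return validated configuration list
#' @export
pipelineConfig <- function(config = NULL) {
  base <- .defaultPipelineConfig()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(base, config)
  for (f in c("input", "roles", "input2", "roles2", "phenotype"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file does not exist: ", cfg[[f]])
  cfg
}

.stageLog <- function(stage, ...) {
  message(sprintf("[gbsf2] %s: %s", stage, paste(..., collapse = " ")))
}

.filterStage <- function(m, fp) {
  m <- filterParentalConsistency(m)
  m <- filterMAF(m, threshold = fp$maf)
  m <- maskLowDepth(m, minDepth = fp$min_depth)
  m <- thinSites(m, minBp = fp$thin_bp)
  m <- filterSiteMissingness(m, maxMissing = fp$max_missing)
  m
}

#' Run the GBS post-processing pipeline
#'
#' Executes the enabled stages in the fixed order filter, encode, impute,
#' correct, merge (when a second population is configured), map, scan.
#' Every stage persists its output under \code{out_dir} and logs per-stage
#' counts to stderr; a provenance record (configuration, seed, package
#' version) sufficient to reproduce the run is written as JSON. A stage
#' failure aborts with the stage name; outputs of completed stages are
#' retained.
#'
#' @param config list or YAML path accepted by \code{\link{pipelineConfig}}
#' @return named list of in-memory stage artifacts
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(config = cfg)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  process <- function(input, format, roles, tag) {
    m <- wrap("read", readSiteMatrix(input, format = format, roles = roles))
    .stageLog("read", nMarkers(m), "sites,", nSamples(m), "samples", tag)
    if (isTRUE(cfg$stages$filter)) {
      m <- wrap("filter", .filterStage(m, cfg$filter))
      writeFilterReport(m, file.path(cfg$out_dir,
                                     paste0("filter_report", tag, ".json")))
      .stageLog("filter", nMarkers(m), "sites retained", tag)
    }
    if (!isTRUE(cfg$stages$encode)) return(list(site = m, abh = NULL))
    g <- wrap("encode", encodeABH(m))
    writeABHMatrix(g, file.path(cfg$out_dir, paste0("encoded", tag, ".abh.csv")))
    if (isTRUE(cfg$stages$impute)) {
      g <- wrap("impute", imputeFlankedMissing(g))
      writeABHMatrix(g, file.path(cfg$out_dir, paste0("imputed", tag, ".abh.csv")))
    }
    if (isTRUE(cfg$stages$correct)) {
      g <- wrap("correct", correctShortStretches(
        correctUndercalledHet(g, cfg$correct$het_run_max),
        cfg$correct$stretch_run_max))
      writeABHMatrix(g, file.path(cfg$out_dir, paste0("corrected", tag, ".abh.csv")))
    }
    list(site = m, abh = g)
  }
  p1 <- process(cfg$input, cfg$format, cfg$roles, "")
  artifacts$site <- p1$site
  g <- p1$abh
  if (isTRUE(cfg$stages$merge) && !is.null(cfg$input2)) {
    p2 <- process(cfg$input2, cfg$format2, cfg$roles2, "_pop2")
    g <- wrap("merge", mergePopulations(g, p2$abh))
    writeABHMatrix(g, file.path(cfg$out_dir, "merged.abh.csv"))
    .stageLog("merge", nMarkers(g), "markers,", nSamples(g), "individuals")
  }
  artifacts$abh <- g
  if (!is.null(g) && isTRUE(cfg$stages$map)) {
    map <- wrap("map", estimateMap(g, mapFunction = cfg$map$map_function))
    writeMapTSV(map, file.path(cfg$out_dir, "map.tsv"))
    .stageLog("map", round(totalMapLength(map), 1), "cM total")
    artifacts$map <- map
    if (isTRUE(cfg$stages$scan) && !is.null(cfg$phenotype)) {
      phen <- readPhenotype(cfg$phenotype)
      scan <- wrap("scan", qtlScan(
        g, map, phen, stepCM = cfg$scan$step_cm, nDraws = cfg$scan$n_draws,
        nPerm = cfg$scan$n_perm, alpha = cfg$scan$alpha,
        prob = cfg$scan$prob, seed = cfg$seed))
      utils::write.table(lodProfile(scan),
                         file.path(cfg$out_dir, "scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(threshold = scan@threshold, alpha = scan@alpha,
             peaks = scanPeaks(scan)),
        file.path(cfg$out_dir, "peaks.json"), auto_unbox = TRUE, digits = NA)
      artifacts$scan <- scan
    }
  }
  prov <- list(package = "gbsf2",
               version = as.character(utils::packageVersion("gbsf2")),
               seed = cfg$seed, config = cfg)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(artifacts)
}

#' Export graphical genotypes as a long-format table
#'
#' One row per (individual, marker) with the ABH code: the tabular form of
#' the classic graphical-genotype plot (one horizontal colour track per
#' individual along each chromosome).
#'
#' @param g an ABHMatrix
#' @param path optional TSV output path
#' @return data.frame: individual, marker, chrom, pos, code
#' @export
exportGraphicalGenotypes <- function(g, path = NULL) {
  stopifnot(is(g, "ABHMatrix"))
  tb <- data.frame(
    individual = rep(rownames(g@codes), times = ncol(g@codes)),
    marker = rep(g@markers$id, each = nrow(g@codes)),
    chrom = rep(g@markers$chrom, each = nrow(g@codes)),
    pos = rep(g@markers$pos, each = nrow(g@codes)),
    code = as.vector(g@codes),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tb
}

#' Plot graphical genotypes
#'
#' @param g an ABHMatrix
#' @return a ggplot object: markers in order on x (faceted by chromosome),
#'   individuals on y, tiles coloured by genotype code
#' @export
plotGraphicalGenotypes <- function(g) {
  tb <- exportGraphicalGenotypes(g)
  tb$individual <- factor(tb$individual, levels = rev(rownames(g@codes)))
  ggplot2::ggplot(tb, ggplot2::aes(x = pos, y = individual, fill = code)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#2166ac", B = "#e08214",
                                          H = "#1b7837", N = "#000000")) +
    ggplot2::labs(x = "position", y = "individual", fill = "genotype")
}

#' Cells that differ between two ABH matrices
#'
#' @param before,after ABHMatrix objects with identical individuals and
#'   markers
#' @return data.frame: individual, marker, before, after
#' @export
diffGenotypes <- function(before, after) {
  stopifnot(identical(dim(before@codes), dim(after@codes)))
  idx <- which(before@codes != after@codes, arr.ind = TRUE)
  data.frame(individual = rownames(before@codes)[idx[, 1]],
             marker = colnames(before@codes)[idx[, 2]],
             before = before@codes[idx],
             after = after@codes[idx],
             stringsAsFactors = FALSE)
}
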