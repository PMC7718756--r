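# Tabular readers/writers (UTF-8 CSV with '#' metadata headers) binding
# the pipeline stages, and the pipeline orchestrator.

.pkg_version <- function() {
  as.character(utils::packageVersion("pellicle"))
}

# Polynomial rolling hash of a string (mod 2^31 - 1), for config
# fingerprints in output headers (stable, dependency-free).
.config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a data frame as CSV with metadata header
#'
#' Writes `# key: value` comment lines (tool version always included)
#' followed by a standard CSV body. [read_pellicle_csv()] reads it back,
#' exposing the metadata as an attribute.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named list/vector of metadata values (e.g. seed, config
#'   hash).
#' @return `path`, invisibly.
#' @export
write_pellicle_csv <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("pellicle ", .pkg_version())), meta)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pellicle_csv
#' @export
read_pellicle_csv <- function(path) {
  lines <- readLines(path, n = 100, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  attr(df, "meta") <- meta
  df
}

#' Read a genetic map CSV
#'
#' Columns `group, marker, cM` and optionally `bp`.
#'
#' @param path CSV path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  genetic_map(df$group, df$marker, df$cM,
              if ("bp" %in% names(df)) df$bp else NULL)
}

#' Read a pseudo-testcross genotype CSV
#'
#' First column individual id, remaining columns markers, cells `A`, `H` or
#' empty/NA.
#'
#' @param path CSV path.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m)
}

#' Read a pedigree CSV
#'
#' Columns `id, sire, dam`; `0` or empty means unknown.
#'
#' @param path CSV path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character")
  pedigree(df$id, df$sire, df$dam)
}

#' Run the phenotyping pipeline from a configuration
#'
#' Orchestrates tray scoring over a batch of images: reads the calibration
#' model, processes each tray (`white balance -> calibration ->
#' segmentation -> well assignment -> measurement -> DFA class`), and
#' writes a per-kernel scores CSV whose header records the tool version,
#' a configuration hash and the seed, so identical configurations produce
#' identical outputs.
#'
#' @param config named list (or path to a JSON file) with elements
#'   `images` (character vector), `wb` (white-balance image path), `model`
#'   (calibration JSON path), `out` (output CSV path) and optional
#'   `layout` (list with `rows, cols, tray_bbox`), `delta_e_threshold`,
#'   `min_area`, `dfa_cuts` (length 3), `seed`.
#' @return the combined kernel data frame, invisibly; the scores CSV is
#'   written to `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (f in c("images", "wb", "model", "out"))
    if (is.null(config[[f]]))
      stop(sprintf("config field '%s' is required", f), call. = FALSE)
  for (p in c(config$images, config$wb, config$model))
    if (!file.exists(p))
      stop(sprintf("input file not found: %s", p), call. = FALSE)
  model <- read_calibration(config$model)
  wb <- read_rgb_image(config$wb)
  cuts <- if (!is.null(config$dfa_cuts))
    do.call(dfa_thresholds, as.list(config$dfa_cuts)) else dfa_thresholds()
  thr <- config$delta_e_threshold %||% 12
  results <- lapply(config$images, function(p) {
    raw <- read_rgb_image(p)
    layout <- if (!is.null(config$layout))
      tray_layout(config$layout$rows %||% 10, config$layout$cols %||% 10,
                  config$layout$tray_bbox)
    else {
      d <- dim(raw)
      tray_layout(10L, 10L, c(round(0.05 * d[2]), round(0.05 * d[1]),
                              d[2] - round(0.05 * d[2]),
                              d[1] - round(0.05 * d[1])))
    }
    process_tray(raw, wb, model, layout, delta_e_threshold = thr,
                 min_area = config$min_area, dfa_cuts = cuts,
                 tray_id = tools::file_path_sans_ext(basename(p)))
  })
  kernels <- do.call(rbind, lapply(results, `[[`, "kernels"))
  # fingerprint the analytic configuration, not the output location
  keys <- setdiff(sort(names(config)), "out")
  cfg_json <- jsonlite::toJSON(config[keys], auto_unbox = TRUE)
  write_pellicle_csv(kernels, config$out,
                     meta = list(config_hash = .config_hash(as.character(cfg_json)),
                                 seed = config$seed %||% "none"))
  invisible(kernels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
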