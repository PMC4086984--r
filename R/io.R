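# CSV dialect: comma-separated, UTF-8, '.' decimal, mandatory header --
# fixed rather than sniffed, for reproducibility across locales. Angles are
# serialized with "%.17g" so that write/read round-trips reproduce doubles.

cycle_csv_header <- c("cycle_id", "pct", "flexion_deg", "abduction_deg",
                      "rotation_deg")

#' Read gait cycles from CSV
#'
#' Expects columns `cycle_id, pct, flexion_deg, abduction_deg,
#' rotation_deg` with one row per sample. Each `cycle_id` group must hold
#' exactly 101 rows with `pct` 0..100; violations are reported with the
#' file and cycle id.
#'
#' @param path CSV file path.
#' @return named list of [angle_cycle()] matrices, one per cycle id.
#' @export
read_cycles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cycle_id = "character"))
  if (!identical(names(df), cycle_csv_header))
    stop(path, ": header must be exactly ",
         paste(cycle_csv_header, collapse = ","))
  num <- df[, 2:5]
  bad <- which(!vapply(num, is.numeric, logical(1)))
  if (length(bad))
    stop(path, ": non-numeric values in column(s) ",
         paste(names(num)[bad], collapse = ", "))
  if (anyNA(num))
    stop(path, ": missing values in row(s) ",
         paste(utils::head(which(rowSums(is.na(num)) > 0), 5), collapse = ", "))
  if (anyDuplicated(df[, c("cycle_id", "pct")]))
    stop(path, ": duplicate (cycle_id, pct) pair(s)")
  ids <- unique(df$cycle_id)
  out <- lapply(ids, function(id) {
    g <- df[df$cycle_id == id, ]
    if (nrow(g) != 101L)
      stop(path, ": cycle '", id, "' has ", nrow(g), " rows, expected 101")
    if (!isTRUE(all.equal(as.numeric(sort(g$pct)), as.numeric(0:100))))
      stop(path, ": cycle '", id, "' must sample pct 0..100")
    g <- g[order(g$pct), ]
    angle_cycle(as.matrix(g[, 3:5]))
  })
  names(out) <- ids
  out
}

#' Write gait cycles to CSV
#'
#' Inverse of [read_cycles()]; angles are written in full double precision
#' so a write/read round trip is lossless.
#'
#' @param cycles list of 101 x 3 cycle matrices (named or not).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(cycles, path) {
  if (is.matrix(cycles)) cycles <- list(cycles)
  ids <- names(cycles)
  if (is.null(ids)) ids <- sprintf("C%03d", seq_along(cycles))
  rows <- lapply(seq_along(cycles), function(i) {
    m <- angle_cycle(cycles[[i]])
    data.frame(cycle_id = ids[i], pct = 0:100,
               flexion_deg = sprintf("%.17g", m[, 1]),
               abduction_deg = sprintf("%.17g", m[, 2]),
               rotation_deg = sprintf("%.17g", m[, 3]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a dataset manifest
#'
#' JSON manifest tying a dataset together: per-subject cycle files, sides,
#' posture angles, optional ground truth, the Cardan convention, and
#' seed/config provenance.
#'
#' @param path output JSON path.
#' @param subjects data frame (or list) with at least `subject`, `side`
#'   and `file` entries; optional `posture` and `truth`.
#' @param convention a [cardan_convention()].
#' @param config optional generator configuration to embed.
#' @param dataset_id dataset identifier.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subjects,
                           convention = cardan_convention(),
                           config = NULL, dataset_id = "dataset") {
  convention <- as_convention(convention)
  manifest <- list(
    dataset_id = dataset_id,
    convention = list(axes = convention$axes, signs = convention$signs,
                      labels = convention$labels),
    seed = if (!is.null(config)) config$seed,
    config = if (!is.null(config)) unclass(config),
    subjects = subjects)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path JSON manifest path written by [write_manifest()].
#' @param check_files verify that referenced cycle files exist.
#' @return the manifest as a list; `convention` is restored to a
#'   [cardan_convention()].
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$convention))
    stop(path, ": manifest lacks the Cardan convention")
  m$convention <- cardan_convention(axes = m$convention$axes,
                                    signs = m$convention$signs,
                                    labels = m$convention$labels)
  if (check_files && !is.null(m$subjects$file)) {
    missing <- m$subjects$file[!file.exists(
      file.path(dirname(path), m$subjects$file))]
    if (length(missing))
      stop(path, ": missing cycle file(s): ",
           paste(missing, collapse = ", "))
  }
  m
}

#' Write correction reports
#'
#' Emits the summary table CSV (`table1.csv`: metric, side, mean/SD before
#' and after correction), the per-subject posture comparison CSV
#' (`table2.csv`), and a JSON report holding every subject's transfer
#' matrix, eigenvalues, variance contributions, permutation and signs in
#' full double precision, plus seed/config provenance.
#'
#' @param fits named list of [crosstalk_pca()] fits.
#' @param metrics list of [evaluate_subject()] rows matching `fits`.
#' @param dir output directory (created if needed).
#' @param config optional generator configuration for provenance.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(fits, metrics, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- file.path(dir, "table1.csv")
  t2 <- file.path(dir, "table2.csv")
  js <- file.path(dir, "report.json")
  if (length(metrics)) {
    utils::write.csv(group_summary(metrics), t1, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(metric = character(0), side = character(0),
                                n = integer(0), mean_before = numeric(0),
                                sd_before = numeric(0),
                                mean_after = numeric(0),
                                sd_after = numeric(0)),
                     t1, row.names = FALSE)
  }
  m <- if (length(metrics))
    do.call(rbind, lapply(metrics, as.data.frame))
  posture <- data.frame(subject = character(0),
                        posture_before = numeric(0),
                        posture_after = numeric(0), truth = numeric(0))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (is.null(f$posture_corrected)) next
    truth_val <- NA_real_
    if (!is.null(m) && nm %in% m$subject) {
      r <- m[m$subject == nm, ][1, ]
      if (!is.na(r$posture_error_after))
        truth_val <- f$posture_corrected[2] - r$posture_error_after
    }
    posture <- rbind(posture, data.frame(
      subject = nm,
      posture_before = as.numeric(f$observed$posture[2]),
      posture_after = as.numeric(f$posture_corrected[2]),
      truth = as.numeric(truth_val)))
  }
  utils::write.csv(posture, t2, row.names = FALSE)
  per_subject <- lapply(fits, function(f) list(
    subject = f$observed$subject, side = f$observed$side,
    n_cycles = f$n_cycles,
    P = f$transfer$P,  # row-major via serialization of the matrix rows
    permutation = f$transfer$permutation,
    signs = f$transfer$signs,
    eigenvalues = f$eigen$values,
    var_explained = f$eigen$var_explained))
  jsonlite::write_json(list(seed = if (!is.null(config)) config$seed,
                            config = if (!is.null(config)) unclass(config),
                            subjects = per_subject),
                       js, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(t1, t2, js))
}
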