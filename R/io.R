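# Readers and writers for the four standard plate-experiment tables:
#   readings   — well,time_h,od        (long format, one row per reading)
#   layout     — well,strain,treatment,replicate,role
#   genotypes  — line_id + one column per marker (B/H, empty = missing)
#   marker map — marker_id,chromosome,position
# All files are comma-separated with a header row.

LAYOUT_COLS <- c("well", "strain", "treatment", "replicate", "role")

#' Read a plate-layout table
#'
#' @param path CSV with columns well, strain, treatment, replicate, role.
#' @return a data.frame (one row per well).
#' @export
read_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(LAYOUT_COLS %in% names(lay)))
    fa_stop("format_error", "layout must have columns: %s",
            paste(LAYOUT_COLS, collapse = ", "))
  lay <- lay[LAYOUT_COLS]
  if (anyDuplicated(lay$well))
    fa_stop("format_error", "duplicate well(s) in layout: %s",
            paste(unique(lay$well[duplicated(lay$well)]), collapse = ", "))
  if (any(!nzchar(lay$strain)) || any(!nzchar(lay$treatment)))
    fa_stop("format_error", "layout strain/treatment entries must be non-empty")
  bad <- setdiff(unique(lay$role), c("sample", "bacteria_blank", "media_blank"))
  if (length(bad))
    fa_stop("format_error", "unknown layout role(s): %s", paste(bad, collapse = ", "))
  lay$replicate <- as.integer(lay$replicate)
  lay
}

#' @rdname read_layout
#' @param layout a layout data.frame.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout[LAYOUT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format plate readings into fitness curves
#'
#' @param path CSV with columns well, time_h, od.
#' @param layout layout data.frame (see [read_layout()]); every well in the
#'   readings must appear in it.
#' @return a named list of [fitness_curve()] objects (names = wells), with
#'   timepoints sorted ascending regardless of row order in the file.
#' @export
read_readings <- function(path, layout) {
  rd <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "time_h", "od") %in% names(rd)))
    fa_stop("format_error", "readings must have columns: well, time_h, od")
  if (!is.numeric(rd$od) || !is.numeric(rd$time_h))
    fa_stop("format_error", "non-numeric time_h or od values in '%s'", path)
  unknown <- setdiff(unique(rd$well), layout$well)
  if (length(unknown))
    fa_stop("layout_error", "well(s) absent from layout: %s",
            paste(unknown, collapse = ", "))
  if (anyDuplicated(rd[c("well", "time_h")]))
    fa_stop("format_error", "duplicate (well, time) reading(s) in '%s'", path)
  idx <- match(layout$well, unique(rd$well))
  wells <- layout$well[!is.na(idx)]
  curves <- lapply(wells, function(w) {
    sub <- rd[rd$well == w, ]
    sub <- sub[order(sub$time_h), ]
    meta <- layout[layout$well == w, ]
    fitness_curve(well = w, strain = meta$strain, treatment = meta$treatment,
                  replicate = meta$replicate, role = meta$role,
                  time_h = sub$time_h, od = sub$od)
  })
  names(curves) <- wells
  curves
}

#' @rdname read_readings
#' @param curves list of fitness curves to serialize.
#' @export
write_readings <- function(curves, path) {
  df <- curves_to_df(curves)
  utils::write.csv(df[c("well", "time_h", "od")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a RIL genotype matrix
#'
#' Genotypes are stored as line_id plus one column per marker with alleles
#' \code{"B"} (Bristol/N2), \code{"H"} (Hawaii/CB4856); empty or \code{NA}
#' cells are missing calls. RILs are inbred, so no heterozygote coding exists.
#'
#' @param path CSV path.
#' @return a character matrix, lines x markers.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "line_id")
    fa_stop("format_error", "genotype table must start with a line_id column")
  m <- as.matrix(df[-1L])
  rownames(m) <- df$line_id
  m[m == ""] <- NA_character_
  bad <- setdiff(unique(m[!is.na(m)]), c("B", "H"))
  if (length(bad))
    fa_stop("format_error", "invalid allele code(s): %s", paste(bad, collapse = ", "))
  m
}

#' @rdname read_genotypes
#' @param genotypes lines x markers character matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read/write a marker map
#'
#' @param path CSV with columns marker_id, chromosome, position.
#' @return a \code{marker_map} data.frame ordered by (chromosome, position).
#' @export
read_marker_map <- function(path) {
  mp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "chromosome", "position") %in% names(mp)))
    fa_stop("format_error", "marker map must have columns marker_id, chromosome, position")
  as_marker_map(mp)
}

as_marker_map <- function(mp) {
  mp <- mp[order(mp$chromosome, mp$position), , drop = FALSE]
  rownames(mp) <- NULL
  if (anyDuplicated(mp$marker_id))
    fa_stop("format_error", "duplicate marker_id(s) in map")
  inc <- unlist(tapply(mp$position, mp$chromosome,
                       function(p) diff(p) > 0), use.names = FALSE)
  if (length(inc) && !all(inc))
    fa_stop("format_error", "positions must be strictly increasing within chromosomes")
  class(mp) <- c("marker_map", "data.frame")
  mp
}

#' @rdname read_marker_map
#' @param map marker-map data.frame.
#' @export
write_marker_map <- function(map, path) {
  utils::write.csv(as.data.frame(map)[c("marker_id", "chromosome", "position")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated experiment bundle to a directory
#'
#' Emits readings.csv, layout.csv, genotypes.csv, marker_map.csv and, when a
#' ground-truth record is present, truth.json.
#'
#' @param bundle an \code{experiment_bundle} (see [simulate_experiment()]).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  if (!inherits(bundle, "experiment_bundle"))
    fa_stop("parameter_error", "'bundle' must be an experiment_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_readings(bundle$curves, file.path(dir, "readings.csv"))
  write_layout(bundle$layout, file.path(dir, "layout.csv"))
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.csv"))
  write_marker_map(bundle$map, file.path(dir, "marker_map.csv"))
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment bundle from a directory written by [write_experiment()]
#'
#' @param dir directory containing the four CSV tables (truth.json optional).
#' @return an \code{experiment_bundle}.
#' @export
read_experiment <- function(dir) {
  layout <- read_layout(file.path(dir, "layout.csv"))
  curves <- read_readings(file.path(dir, "readings.csv"), layout)
  genotypes <- read_genotypes(file.path(dir, "genotypes.csv"))
  map <- read_marker_map(file.path(dir, "marker_map.csv"))
  tf <- file.path(dir, "truth.json")
  truth <- if (file.exists(tf)) jsonlite::read_json(tf, simplifyVector = TRUE) else NULL
  new_bundle(curves, layout, genotypes, map, truth)
}

new_bundle <- function(curves, layout, genotypes, map, truth = NULL) {
  sample_wells <- layout$well[layout$role == "sample"]
  missing <- setdiff(sample_wells, vapply(curves, `[[`, "", "well"))
  if (length(missing))
    fa_stop("format_error", "sample well(s) without readings: %s",
            paste(missing, collapse = ", "))
  structure(list(curves = curves, layout = layout, genotypes = genotypes,
                 map = map, truth = truth),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d curves | %d lines x %d markers | %d treatments\n",
              length(x$curves), nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$layout$treatment))))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: causal marker %s (seed %s)\n",
                x$truth$causal_marker, x$truth$seed))
  invisible(x)
}
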