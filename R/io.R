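# Plain-text interchange formats: BOLD as TSV (time x region) with a
# JSON sidecar carrying the TR, masks as x,y,z CSV, connectomes as dense
# TSV with a node-label header, streamlines as blank-line-separated
# vertex lists, cohort manifests as JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a connectome as dense TSV with a label header
#'
#' @param c A `connectome`.
#' @param path Output file.
#' @export
write_connectome_tsv <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  df <- as.data.frame(c$weights)
  names(df) <- c$node_labels
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @param active_mask,log_scale Metadata not carried by the TSV itself.
#' @export
read_connectome_tsv <- function(path, active_mask = NULL, log_scale = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  connectome(m, colnames(df), active_mask, log_scale)
}

#' Write / read per-region BOLD series as TSV plus a JSON sidecar
#'
#' Rows are time points, columns are regions (header row of region
#' labels); the sidecar records `tr_seconds`.
#'
#' @param series Named list of [bold_series()] with a common TR.
#' @param path Output TSV; the sidecar is `<path>.json`.
#' @export
write_bold_tsv <- function(series, path) {
  trs <- unique(vapply(series, `[[`, numeric(1), "tr_seconds"))
  if (length(trs) != 1L) stop_data("series in one file must share a TR")
  df <- as.data.frame(lapply(series, `[[`, "values"))
  names(df) <- names(series)
  write_tsv(df, path)
  jsonlite::write_json(list(tr_seconds = trs), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @export
read_bold_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tr <- jsonlite::read_json(paste0(path, ".json"))$tr_seconds
  out <- lapply(names(df), function(nm) bold_series(df[[nm]], tr, nm))
  names(out) <- names(df)
  out
}

#' Write / read a voxel mask as 3-column integer CSV
#'
#' @param mask Integer matrix (n x 3).
#' @param path Output CSV with header `x,y,z`.
#' @export
write_mask_csv <- function(mask, path) {
  df <- as.data.frame(mask)
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}

#' Write / read streamlines as a simple multi-polyline text format
#'
#' One vertex (`x y z`) per line; blank lines separate streamlines.
#'
#' @param streamlines List of numeric matrices (vertices x 3).
#' @param path Output file.
#' @export
write_streamlines_txt <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in streamlines) {
    if (is.null(dim(s))) s <- matrix(s, ncol = 3)
    writeLines(apply(format(s, trim = TRUE, scientific = FALSE), 1L,
                     paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_streamlines_txt
#' @export
read_streamlines_txt <- function(path) {
  lines <- readLines(path)
  groups <- split(lines, cumsum(lines == ""))
  out <- lapply(groups, function(g) {
    g <- g[g != ""]
    if (length(g) == 0L) return(NULL)
    do.call(rbind, lapply(strsplit(g, "\\s+"), as.numeric))
  })
  Filter(Negate(is.null), unname(out))
}

#' Write a synthetic cohort as a directory tree
#'
#' Per subject: BOLD TSV (+ TR sidecar), tumor mask CSV (patients),
#' connectome TSVs; shared DMN region masks; a JSON manifest describing
#' every subject and the generator configuration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$dmn_masks)) {
    mdir <- file.path(dir, "dmn_masks")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(cohort$dmn_masks)) {
      write_mask_csv(cohort$dmn_masks[[i]],
                     file.path(mdir, sprintf("dmn_%02d.csv", i)))
    }
  }
  manifest <- lapply(cohort$subjects, function(s) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    if (!is.null(s$bold)) write_bold_tsv(s$bold, file.path(sdir, "bold.tsv"))
    if (!is.null(s$tumor_mask)) {
      write_mask_csv(s$tumor_mask, file.path(sdir, "tumor_mask.csv"))
    }
    write_connectome_tsv(s$pre_connectome, file.path(sdir, "connectome_pre.tsv"))
    if (!is.null(s$post_connectome)) {
      write_connectome_tsv(s$post_connectome, file.path(sdir, "connectome_post.tsv"))
    }
    list(subject_id = s$subject_id, role = s$role,
         tr_seconds = s$tr_seconds, true_tilt = s$true_tilt,
         lesion_label = s$lesion_label,
         periventricular = s$periventricular,
         tumor_volume_voxels = s$tumor_volume_voxels,
         true_surgery_edges = s$true_surgery_edges)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = cohort$seed,
                            config = cohort$config[!vapply(cohort$config, is.null, logical(1))],
                            subjects = manifest),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
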