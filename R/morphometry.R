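# Vertex-wise morphometry ingestion, validation and parcel summaries.

VERTEX_COLUMNS <- c("subject_id", "hemisphere", "vertex_index",
                    "parcel_label", "volume", "area", "thickness")
MEASURES <- c("volume", "area", "thickness")

#' Construct a subject morphometry object
#'
#' Holds, for one subject, the multiset of vertex-level values of each
#' morphometric measure per cortical parcel, plus whole-cortex summaries
#' (total volume, total area, mean thickness) used as the global
#' morphometry covariate in the interaction model.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param parcels Named list, one element per parcel (names are parcel
#'   labels, e.g. `"Vis(lh)"`), each a list with numeric vectors `volume`,
#'   `area`, `thickness` of equal length (one entry per vertex).
#' @return An object of class `subject_morphometry` with elements
#'   `subject_id`, `parcels`, `vertex_count` (named integer vector) and
#'   `totals` (list with `total_volume`, `total_area`, `mean_thickness`).
#' @export
subject_morphometry <- function(subject_id, parcels) {
  if (length(subject_id) != 1L) stop("'subject_id' must be scalar", call. = FALSE)
  if (!length(parcels) || is.null(names(parcels)) || anyDuplicated(names(parcels))) {
    stop("'parcels' must be a non-empty uniquely named list", call. = FALSE)
  }
  for (p in names(parcels)) {
    lens <- lengths(parcels[[p]][MEASURES])
    if (length(unique(lens)) != 1L || lens[1L] < 1L) {
      stop(sprintf("parcel '%s': measures must be non-empty vectors of equal length", p),
           call. = FALSE)
    }
  }
  out <- structure(list(
    subject_id   = as.character(subject_id),
    parcels      = parcels,
    vertex_count = vapply(parcels, function(p) length(p$volume), integer(1L)),
    totals       = NULL
  ), class = "subject_morphometry")
  out$totals <- compute_totals(out)
  out
}

compute_totals <- function(sm) {
  list(
    total_volume   = sum(unlist(lapply(sm$parcels, `[[`, "volume"), use.names = FALSE)),
    total_area     = sum(unlist(lapply(sm$parcels, `[[`, "area"), use.names = FALSE)),
    mean_thickness = mean(unlist(lapply(sm$parcels, `[[`, "thickness"), use.names = FALSE))
  )
}

#' @export
print.subject_morphometry <- function(x, ...) {
  cat(sprintf("Subject morphometry '%s': %d parcels, %d vertices\n",
              x$subject_id, length(x$parcels), sum(x$vertex_count)))
  cat(sprintf("  total volume %.1f mm^3, total area %.1f mm^2, mean thickness %.3f mm\n",
              x$totals$total_volume, x$totals$total_area, x$totals$mean_thickness))
  invisible(x)
}

#' Read a vertex-wise morphometry table
#'
#' Reads a tab-delimited table with one row per cortical-surface vertex and
#' columns `subject_id`, `hemisphere` (`lh`/`rh`), `vertex_index`,
#' `parcel_label`, `volume` (mm^3), `area` (mm^2), `thickness` (mm), and
#' returns one [subject_morphometry()] object per subject. Parcel order is
#' the order of first appearance in the file and is preserved downstream
#' (it defines similarity-matrix row order).
#'
#' @param path Path to the TSV file.
#' @return A named list of class `morphometry_set`, one
#'   `subject_morphometry` per subject.
#' @export
read_vertex_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  missing <- setdiff(VERTEX_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("vertex table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("vertex table contains no data rows", call. = FALSE)
  validate_vertex_frame(df)
  morphometry_from_frame(df)
}

validate_vertex_frame <- function(df) {
  bad_hemi <- which(!df$hemisphere %in% c("lh", "rh"))
  if (length(bad_hemi)) {
    stop(sprintf("invalid hemisphere at row(s) %s (must be 'lh' or 'rh')",
                 paste(head(bad_hemi, 5L), collapse = ", ")), call. = FALSE)
  }
  for (m in MEASURES) {
    v <- df[[m]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("negative or non-finite %s at row(s) %s",
                   m, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  if (any(df$vertex_index < 0)) stop("vertex_index must be non-negative", call. = FALSE)
  key <- paste(df$subject_id, df$hemisphere, df$vertex_index)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (subject, hemisphere, vertex) at row(s) %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

morphometry_from_frame <- function(df) {
  subjects <- unique(df$subject_id)
  out <- lapply(subjects, function(s) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    labels <- unique(sub$parcel_label)
    parcels <- lapply(labels, function(lbl) {
      rows <- sub$parcel_label == lbl
      list(volume = sub$volume[rows], area = sub$area[rows],
           thickness = sub$thickness[rows])
    })
    names(parcels) <- labels
    subject_morphometry(s, parcels)
  })
  names(out) <- subjects
  structure(out, class = "morphometry_set")
}

#' @export
print.morphometry_set <- function(x, ...) {
  cat(sprintf("Morphometry set: %d subject(s)\n", length(x)))
  invisible(x)
}

#' Write subject morphometry back to a vertex table
#'
#' Inverse of [read_vertex_table()]; vertex indices are regenerated
#' sequentially within hemisphere. Used by the synthetic-cohort generator
#' and the pipeline round-trips.
#'
#' @param x A `morphometry_set` or single `subject_morphometry`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_table <- function(x, path) {
  if (inherits(x, "subject_morphometry")) x <- structure(list(x), class = "morphometry_set",
                                                         names = x$subject_id)
  frames <- lapply(x, function(sm) {
    per_parcel <- lapply(names(sm$parcels), function(lbl) {
      p <- sm$parcels[[lbl]]
      hemi <- if (grepl("\\(rh\\)", lbl)) "rh" else "lh"
      data.frame(subject_id = sm$subject_id, hemisphere = hemi,
                 vertex_index = NA_integer_, parcel_label = lbl,
                 volume = p$volume, area = p$area, thickness = p$thickness,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_parcel)
    for (h in c("lh", "rh")) {
      rows <- df$hemisphere == h
      df$vertex_index[rows] <- seq_len(sum(rows)) - 1L
    }
    df
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Drop parcels with too few vertices
#'
#' Parcels whose vertex count is below `min_vertices` are excluded; the
#' default keeps parcels with at least 50 vertices (strictly fewer than 50
#' are removed). Whole-cortex summaries are recomputed over the retained
#' parcels only. Parcel order is preserved.
#'
#' @param sm A `subject_morphometry` or `morphometry_set`.
#' @param min_vertices Minimum vertex count for a parcel to be retained.
#' @return Object of the same class with only the retained parcels.
#' @export
filter_parcels <- function(sm, min_vertices = 50L) {
  stopifnot_scalar_count(min_vertices, "min_vertices")
  if (inherits(sm, "morphometry_set")) {
    out <- lapply(sm, filter_parcels, min_vertices = min_vertices)
    return(structure(out, class = "morphometry_set", names = names(sm)))
  }
  if (!inherits(sm, "subject_morphometry")) {
    stop("'sm' must be a subject_morphometry or morphometry_set", call. = FALSE)
  }
  keep <- sm$vertex_count >= min_vertices
  if (sum(keep) < 3L) {
    stop(sprintf("subject '%s': only %d parcel(s) with >= %d vertices; need at least 3 for a network",
                 sm$subject_id, sum(keep), min_vertices), call. = FALSE)
  }
  subject_morphometry(sm$subject_id, sm$parcels[keep])
}

#' Per-parcel morphometry summaries
#'
#' Totals are sums of vertex values within the parcel (volume, area); mean
#' thickness is the arithmetic mean over the parcel's vertices.
#'
#' @param sm A `subject_morphometry`.
#' @return A data.frame with columns `parcel`, `vertex_count`,
#'   `total_volume`, `total_area`, `mean_thickness`.
#' @export
summarize_parcels <- function(sm) {
  if (!inherits(sm, "subject_morphometry")) {
    stop("'sm' must be a subject_morphometry", call. = FALSE)
  }
  data.frame(
    parcel         = names(sm$parcels),
    vertex_count   = unname(sm$vertex_count),
    total_volume   = vapply(sm$parcels, function(p) sum(p$volume), numeric(1L), USE.NAMES = FALSE),
    total_area     = vapply(sm$parcels, function(p) sum(p$area), numeric(1L), USE.NAMES = FALSE),
    mean_thickness = vapply(sm$parcels, function(p) mean(p$thickness), numeric(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# Whole-cortex covariate matched to a network measure: total volume for the
# volume network, total area for the area network, mean thickness for the
# thickness network.
global_morph_covariate <- function(sm, measure) {
  measure <- match.arg(measure, MEASURES)
  switch(measure,
         volume = sm$totals$total_volume,
         area = sm$totals$total_area,
         thickness = sm$totals$mean_thickness)
}

#' Read a cohort covariate table
#'
#' @param path TSV with columns `subject_id`, `age` (years), `sex` (0/1),
#'   `education` (years), `icv` (mm^3) and one numeric column per behavior
#'   score.
#' @return A data.frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  required <- c("subject_id", "age", "sex", "education", "icv")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("cohort table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}
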