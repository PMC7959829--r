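# Small fixtures built in code at test time.

# A tiny parcellation with homologous left/right pairs (planted by
# default in cohort_spec) plus unpaired parcels.
small_parcellation <- function(P = 8L, vertices = 60L) {
  base <- LETTERS[seq_len(ceiling(P / 2))]
  parcel <- as.vector(rbind(sprintf("%s(lh)", base), sprintf("%s(rh)", base)))[seq_len(P)]
  data.frame(parcel = parcel,
             hemisphere = ifelse(grepl("\\(rh\\)", parcel), "rh", "lh"),
             vertex_count = rep_len(vertices, P),
             stringsAsFactors = FALSE)
}

small_spec <- function(n_subjects = 20L, P = 8L, vertices = 60L, seed = 11L, ...) {
  cohort_spec(n_subjects = n_subjects, parcels = small_parcellation(P, vertices),
              seed = seed, ...)
}

# A subject with explicitly chosen parcel value multisets; area/thickness
# default to scaled copies of volume.
toy_subject <- function(volumes, id = "toy") {
  parcels <- lapply(volumes, function(v) {
    list(volume = v, area = v / 2, thickness = pmin(v / 10 + 1, 5))
  })
  subject_morphometry(id, parcels)
}

# Write a vertex-table TSV from rows given as a data.frame.
write_vertex_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

vertex_rows <- function(subject_id, parcel_label, volume,
                        hemisphere = "lh", vertex_index = NULL,
                        area = volume / 2, thickness = 2.5) {
  n <- length(volume)
  data.frame(subject_id = rep_len(subject_id, n),
             hemisphere = rep_len(hemisphere, n),
             vertex_index = vertex_index %||% (seq_len(n) - 1L),
             parcel_label = rep_len(parcel_label, n), volume = volume,
             area = rep_len(area, n), thickness = rep_len(thickness, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip class and metadata attributes, keeping values and dimnames.
strip_attrs <- function(M) {
  M <- unclass(M)
  attributes(M) <- attributes(M)[c("dim", "dimnames")]
  M
}

# Cohort design for GLM-level simulations: covariates from a spec plus a
# directly drawn efficiency column (the fit's statistical properties do
# not depend on where E came from).
glm_design <- function(n = 65L, seed = 1L) {
  spec <- cohort_spec(n_subjects = n, seed = seed)
  d <- simulate_covariates(spec)
  d$morph_global <- stats::rnorm(n, 9e4, 5e3)
  d$e_glob <- stats::rnorm(n)
  d
}

default_coefs <- function(interaction = -0.3) {
  c(age = 0.3, efficiency = 0.3, sex = 0.2, education = 0.2, icv = 0.1,
    morph = 0.2, interaction = interaction, intercept = 0)
}
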