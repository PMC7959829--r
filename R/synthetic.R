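# Synthetic cohorts for validating the pipeline end to end: vertex-wise
# morphometry with controllable cross-parcel distribution similarity,
# covariates, and behavior scores generated from the interaction model's
# forward equation, with network efficiency taken from the real pipeline
# run on the synthetic morphometry.

#' The 32-parcel cortical parcellation used by default
#'
#' The 32 parcels of the 51-parcel functional parcellation that survive
#' the 50-vertex filter on the fsaverage5 surface, with their vertex
#' counts. Hemisphere is carried in the label, e.g. `"Vis(lh)"`.
#'
#' @return A data.frame with columns `parcel`, `hemisphere`,
#'   `vertex_count`.
#' @export
yeo32_parcellation <- function() {
  lh <- c(Vis = 1213L, SomMot = 1590L, DorsAttn_Post = 627L,
          DorsAttn_FEF = 97L, SalVentAttn_ParOper = 130L,
          SalVentAttn_FrOper = 331L, SalVentAttn_Med = 216L,
          Limbic_OFC = 213L, Limbic_TempPole = 331L, Cont_Par = 151L,
          Cont_PFCl = 291L, Default_Par = 263L, Default_Temp = 359L,
          Default_PFC = 771L, Default_PCC = 281L)
  rh <- c(Vis = 1266L, SomMot = 1612L, DorsAttn_Post = 614L,
          DorsAttn_FEF = 98L, DorsAttn_PrCv = 50L,
          SalVentAttn_TempOccPar = 208L, SalVentAttn_FrOper = 313L,
          SalVentAttn_Med = 242L, Limbic_OFC = 237L,
          Limbic_TempPole = 321L, Cont_Par = 167L, Cont_PFCl = 543L,
          Default_Par = 183L, Default_Temp = 269L, Default_PFCv = 60L,
          Default_PFCm = 461L, Default_PCC = 225L)
  data.frame(
    parcel = c(sprintf("%s(lh)", names(lh)), sprintf("%s(rh)", names(rh))),
    hemisphere = c(rep("lh", length(lh)), rep("rh", length(rh))),
    vertex_count = c(unname(lh), unname(rh)),
    stringsAsFactors = FALSE
  )
}

default_behaviors <- function() {
  base <- c(age = 0.3, efficiency = 0.3, sex = 0.2, education = 0.2,
            icv = 0.1, morph = 0.2, interaction = -0.3, intercept = 0)
  emo <- base
  emo["interaction"] <- 0.3
  list(cognitive = list(coefficients = base, noise_sd = 0.6),
       emotional = list(coefficients = emo, noise_sd = 0.6))
}

#' Specify a synthetic cohort
#'
#' Fixes every aspect of a simulated cohort: sample size, parcellation,
#' per-parcel vertex-value distributions (log-normal for volume and area,
#' zero-truncated normal for thickness), which parcel pairs share a
#' distribution template (homologous left/right parcels by default, so
#' their distribution similarity is high), covariate generators, and the
#' forward-model coefficients and noise for each behavior. The same spec
#' (including `seed`) always reproduces the same cohort bit for bit.
#'
#' @param n_subjects Number of subjects (default 65).
#' @param parcels Parcellation data.frame as from [yeo32_parcellation()].
#' @param age_range Uniform age range in years (default 18-64).
#' @param education_mean,education_sd Education (years) normal parameters.
#' @param icv_mean,icv_sd Intracranial volume (mm^3) normal parameters.
#' @param behaviors Named list; each element has `coefficients` (named
#'   vector with `age`, `efficiency`, `sex`, `education`, `icv`, `morph`,
#'   `interaction`, `intercept`) and `noise_sd`. Defaults plant a negative
#'   age-by-efficiency interaction in a "cognitive" score and a positive
#'   one in an "emotional" score.
#' @param planted_pairs 2-column character matrix of parcel pairs sharing
#'   a distribution template; `NULL` (default) uses all homologous
#'   left/right pairs.
#' @param jitter_sd Subject-level jitter SD on a template's location
#'   parameter (log scale).
#' @param n_bins Histogram bins used when the pipeline is run.
#' @param seed Integer seed fixing every draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 65L,
                        parcels = yeo32_parcellation(),
                        age_range = c(18, 64),
                        education_mean = 15.4, education_sd = 3.2,
                        icv_mean = 1.45e6, icv_sd = 1.5e5,
                        behaviors = default_behaviors(),
                        planted_pairs = NULL,
                        jitter_sd = 0.05,
                        n_bins = 30L,
                        seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects", min = 4L)
  if (is.null(planted_pairs)) {
    base <- sub("\\((lh|rh)\\)$", "", parcels$parcel)
    both <- names(which(table(base)[unique(base)] == 2L))
    planted_pairs <- cbind(sprintf("%s(lh)", both), sprintf("%s(rh)", both))
  }
  if (length(planted_pairs) &&
      !all(planted_pairs %in% parcels$parcel)) {
    stop("planted pairs reference unknown parcels", call. = FALSE)
  }
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), parcels = parcels,
    age_range = age_range, education_mean = education_mean,
    education_sd = education_sd, icv_mean = icv_mean, icv_sd = icv_sd,
    behaviors = behaviors, planted_pairs = planted_pairs,
    jitter_sd = jitter_sd, n_bins = as.integer(n_bins),
    seed = as.integer(seed)
  ), class = "cohort_spec")
  spec$distributions <- draw_parcel_distributions(spec)
  spec
}

# Per-parcel distribution parameters, drawn once per spec from a dedicated
# seed stream. Planted pairs point at the same template row.
draw_parcel_distributions <- function(spec) {
  parcels <- spec$parcels$parcel
  template_of <- stats::setNames(seq_along(parcels), parcels)
  if (length(spec$planted_pairs)) {
    for (r in seq_len(nrow(spec$planted_pairs))) {
      template_of[spec$planted_pairs[r, 2L]] <-
        template_of[[spec$planted_pairs[r, 1L]]]
    }
  }
  templates <- unique(template_of)
  set.seed(derive_seed(spec$seed, 999L))
  tpl <- data.frame(
    template = templates,
    volume_meanlog = stats::rnorm(length(templates), log(22), 0.15),
    volume_sdlog = stats::runif(length(templates), 0.35, 0.5),
    area_meanlog = stats::rnorm(length(templates), log(9), 0.15),
    area_sdlog = stats::runif(length(templates), 0.3, 0.45),
    thickness_mean = stats::rnorm(length(templates), 2.5, 0.15),
    thickness_sd = stats::runif(length(templates), 0.4, 0.6)
  )
  out <- tpl[match(template_of, tpl$template), ]
  out$parcel <- parcels
  out$vertex_count <- spec$parcels$vertex_count
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d subjects, %d parcels, ages %g-%g, seed %d\n",
              x$n_subjects, nrow(x$parcels), x$age_range[1L], x$age_range[2L],
              x$seed))
  cat(sprintf("  behaviors: %s; %d planted similar pair(s)\n",
              paste(names(x$behaviors), collapse = ", "),
              if (length(x$planted_pairs)) nrow(x$planted_pairs) else 0L))
  invisible(x)
}

rtruncnorm_pos <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  while (any(bad <- v <= 0)) v[bad] <- stats::rnorm(sum(bad), mean, sd)
  v
}

#' Simulate one subject's vertex-wise morphometry
#'
#' Vertex values are drawn per parcel from the spec's distributions, with
#' a subject-level jitter applied to each template's location parameter.
#' Planted parcel pairs share a template (and its jitter), so their value
#' distributions — and hence their histogram similarity — stay high.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index in `1:n_subjects`.
#' @return A [subject_morphometry()] object.
#' @export
simulate_subject_morphometry <- function(spec, subject) {
  stopifnot_scalar_count(subject, "subject")
  if (subject > spec$n_subjects) stop("subject index out of range", call. = FALSE)
  set.seed(derive_seed(spec$seed, subject))
  dist <- spec$distributions
  jit <- stats::rnorm(length(unique(dist$template)), 0, spec$jitter_sd)
  names(jit) <- as.character(unique(dist$template))
  parcels <- vector("list", nrow(dist))
  names(parcels) <- dist$parcel
  for (k in seq_len(nrow(dist))) {
    d <- dist[k, ]
    nv <- d$vertex_count
    j <- jit[[as.character(d$template)]]
    parcels[[k]] <- list(
      volume = stats::rlnorm(nv, d$volume_meanlog + j, d$volume_sdlog),
      area = stats::rlnorm(nv, d$area_meanlog + j, d$area_sdlog),
      thickness = rtruncnorm_pos(nv, d$thickness_mean * exp(j / 4), d$thickness_sd)
    )
  }
  subject_morphometry(sprintf("sub-%03d", subject), parcels)
}

#' Simulate cohort covariates
#'
#' Ages uniform over the spec's range, sex balanced (random assignment),
#' education and intracranial volume from the spec's normal distributions.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with `subject_id`, `age`, `sex`, `education`,
#'   `icv`.
#' @export
simulate_covariates <- function(spec) {
  n <- spec$n_subjects
  set.seed(derive_seed(spec$seed, 0L))
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = stats::runif(n, spec$age_range[1L], spec$age_range[2L]),
    sex = sample(rep_len(c(0L, 1L), n)),
    education = pmax(6, stats::rnorm(n, spec$education_mean, spec$education_sd)),
    icv = stats::rnorm(n, spec$icv_mean, spec$icv_sd),
    stringsAsFactors = FALSE
  )
}

#' Generate behavior scores from the interaction forward model
#'
#' Computes `beh = a1*z(age) + a2*z(E) + a3*sex + a4*z(edu) + a5*z(icv) +
#' a6*z(morph) + beta*z(age)*z(E) + intercept + noise`, with continuous
#' variables z-scored within the supplied cohort, matching the scale on
#' which the model is fitted.
#'
#' @param data Cohort data.frame with `age`, `sex`, `education`, `icv`,
#'   the `morph` column and the `efficiency` column.
#' @param coefficients Named vector (`age`, `efficiency`, `sex`,
#'   `education`, `icv`, `morph`, `interaction`, `intercept`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional seed for the noise draw.
#' @param efficiency,morph Column names.
#' @return Numeric vector of behavior scores.
#' @export
simulate_behavior <- function(data, coefficients, noise_sd = 0, seed = NULL,
                              efficiency = "e_glob", morph = "morph_global") {
  need <- c("age", "efficiency", "sex", "education", "icv", "morph",
            "interaction", "intercept")
  if (!all(need %in% names(coefficients))) {
    stop(sprintf("coefficients must be named: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  z <- function(x) (x - mean(x)) / stats::sd(x)
  za <- z(data$age); ze <- z(data[[efficiency]])
  mu <- coefficients[["age"]] * za +
    coefficients[["efficiency"]] * ze +
    coefficients[["sex"]] * data$sex +
    coefficients[["education"]] * z(data$education) +
    coefficients[["icv"]] * z(data$icv) +
    coefficients[["morph"]] * z(data[[morph]]) +
    coefficients[["interaction"]] * za * ze +
    coefficients[["intercept"]]
  if (!is.null(seed)) set.seed(seed)
  mu + stats::rnorm(length(mu), 0, noise_sd)
}

#' Simulate a full cohort through the real pipeline
#'
#' Draws vertex-wise morphometry and covariates from the spec, then runs
#' the actual network pipeline (parcel filter, histogram similarity, OMST,
#' binary-graph efficiency) on the synthetic morphometry to obtain each
#' subject's efficiency values, and finally generates behavior scores from
#' the interaction forward model. Because efficiency is the pipeline's own
#' output rather than an independently drawn variable, parameter-recovery
#' tests exercise every stage.
#'
#' @param spec A [cohort_spec()].
#' @param measure Which morphometric network to build (default `"area"`).
#' @param progress Print per-subject progress.
#' @return An object of class `synthetic_cohort`: list with `morphometry`
#'   (a `morphometry_set`), `cohort` (data.frame with covariates,
#'   `morph_global`, `e_glob`, per-parcel `e_nodal_*`/`e_local_*` columns
#'   and one column per behavior), `measure`, and `spec`.
#' @export
simulate_cohort <- function(spec, measure = c("area", "volume", "thickness"),
                            progress = FALSE) {
  measure <- match.arg(measure)
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  covars <- simulate_covariates(spec)
  n <- spec$n_subjects

  subjects <- vector("list", n)
  eff <- vector("list", n)
  morph_global <- numeric(n)
  for (i in seq_len(n)) {
    sm <- filter_parcels(simulate_subject_morphometry(spec, i))
    S <- suppressWarnings(build_similarity_matrix(sm, measure, spec$n_bins))
    om <- omst_select(absolutize(S))
    eff[[i]] <- efficiency_profile(om$graph, sm$subject_id, measure)
    morph_global[i] <- global_morph_covariate(sm, measure)
    subjects[[i]] <- sm
    if (progress) message(sprintf("subject %d/%d done", i, n))
  }
  names(subjects) <- vapply(subjects, `[[`, character(1L), "subject_id")

  labels <- eff[[1L]]$labels
  cohort <- covars
  cohort$morph_global <- morph_global
  cohort$e_glob <- vapply(eff, `[[`, numeric(1L), "e_glob")
  nodal <- t(vapply(eff, `[[`, numeric(length(labels)), "e_nodal"))
  local <- t(vapply(eff, `[[`, numeric(length(labels)), "e_local"))
  colnames(nodal) <- sprintf("e_nodal_%s", labels)
  colnames(local) <- sprintf("e_local_%s", labels)
  cohort <- cbind(cohort, as.data.frame(nodal, check.names = FALSE),
                  as.data.frame(local, check.names = FALSE))

  for (b in seq_along(spec$behaviors)) {
    bs <- spec$behaviors[[b]]
    cohort[[names(spec$behaviors)[b]]] <-
      simulate_behavior(cohort, bs$coefficients, bs$noise_sd,
                        seed = derive_seed(spec$seed, 1000L + b))
  }
  structure(list(morphometry = structure(subjects, class = "morphometry_set"),
                 cohort = cohort, measure = measure, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, measure '%s', %d behavior(s)\n",
              nrow(x$cohort), x$measure, length(x$spec$behaviors)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the vertex table, the cohort table (covariates + behaviors, the
#' pipeline's input contract) and a truth file of generator parameters.
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vertex = file.path(dir, "vertices.tsv"),
             cohort = file.path(dir, "cohort.tsv"),
             truth = file.path(dir, "truth.yaml"))
  write_vertex_table(x$morphometry, paths[["vertex"]])
  behaviors <- names(x$spec$behaviors)
  cohort_cols <- c("subject_id", "age", "sex", "education", "icv", behaviors)
  data.table::fwrite(x$cohort[, cohort_cols], paths[["cohort"]], sep = "\t",
                     quote = FALSE)
  truth <- list(seed = x$spec$seed, n_subjects = x$spec$n_subjects,
                measure = x$measure,
                behaviors = lapply(x$spec$behaviors, function(b) {
                  list(coefficients = as.list(b$coefficients),
                       noise_sd = b$noise_sd)
                }))
  yaml::write_yaml(truth, paths[["truth"]])
  invisible(paths)
}
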