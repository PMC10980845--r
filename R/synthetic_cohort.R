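#' Specification of a synthetic lifespan cohort
#'
#' Describes the generative model for a synthetic cohort of resting-state
#' connectomes and cognitive scores with planted ground truth. Connectomes
#' arise from a block factor time-series model: each planted module carries
#' a latent signal; every node loads on its own module's signal (weight
#' `within_coupling(age)`, monotone decreasing with age), on the other
#' modules' signals through node-specific random cross-loadings scaled by
#' `between_coupling(age)` (increasing with a configurable midlife knee;
#' the cross-loadings emulate overlapping resting-state networks and keep
#' thresholded graphs connected), and on a global signal, plus white noise.
#' Fisher-z correlations of the simulated series form the subject's matrix.
#' Cognitive scores load on two latent factors — a domain-general factor
#' declining linearly with age and a semantic factor following an inverted
#' U peaking at the knee age — linked to the connectome through a shared
#' subject-level coupling perturbation.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range numeric length-2, default c(18, 88).
#' @param n_rois number of ROIs (default 131).
#' @param module_sizes planted module sizes; must sum to <= n_rois
#'   (remainder = unassigned ROIs). Default 40/34/32/22 (+3 unassigned).
#' @param within_coupling function(age) -> latent within-module weight;
#'   default decreases linearly from 0.65 at 18 to 0.55 at 88.
#' @param between_coupling function(age) -> between-module coupling scale
#'   (applied to cross-loadings and the global signal); default rises from
#'   0.32 at 18 to 0.355 at `inflection_age` and on to 0.38 at 88.
#' @param inflection_age knee of the default coupling trends (default 55).
#' @param cross_loading_sd scale of the node-specific half-normal
#'   cross-loadings onto other modules (default 0.5; 0 reduces the model
#'   to a pure block one-factor design).
#' @param ts_length simulated time points per subject (default 150).
#' @param noise_sd time-series noise SD (default 0.5).
#' @param cognitive_noise_sd task-score noise SD (default 0.2).
#' @param cognitive_loading 8 x 2 matrix of task loadings on the
#'   (domain-general, semantic) factors; a built-in default spans tasks
#'   from synergy-heavy to memory/comprehension tasks.
#' @param missing_rate per-score missingness probability in \[0, 1)
#'   (default 0.02, completely at random).
#' @param seed integer master seed; fully determines the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        age_range = c(18, 88),
                        n_rois = 131,
                        module_sizes = c(40, 34, 32, 22),
                        within_coupling = NULL,
                        between_coupling = NULL,
                        inflection_age = 55,
                        cross_loading_sd = 0.5,
                        ts_length = 150,
                        noise_sd = 0.5,
                        cognitive_noise_sd = 0.2,
                        cognitive_loading = NULL,
                        missing_rate = 0.02,
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (sum(module_sizes) > n_rois)
    stop("module_sizes sum exceeds n_rois")
  if (ts_length <= 1) stop("ts_length must be > 1")
  if (noise_sd < 0 || cognitive_noise_sd < 0) stop("noise SDs must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  a0 <- age_range[1]; a1 <- age_range[2]
  if (is.null(within_coupling))
    within_coupling <- function(age) 0.65 - 0.10 * (age - a0) / (a1 - a0)
  if (is.null(between_coupling)) {
    between_coupling <- function(age) {
      # piecewise linear with a midlife knee
      pre <- pmin(age, inflection_age) - a0
      post <- pmax(age - inflection_age, 0)
      0.32 + 0.035 * pre / (inflection_age - a0) +
        0.025 * post / (a1 - inflection_age)
    }
  }
  if (cross_loading_sd < 0) stop("cross_loading_sd must be >= 0")
  ages_chk <- seq(a0, a1, length.out = 200)
  if (any(within_coupling(ages_chk) <= between_coupling(ages_chk)))
    stop("degenerate coupling: within_coupling must exceed between_coupling over the age range")
  if (is.null(cognitive_loading)) cognitive_loading <- default_task_loadings()
  cognitive_loading <- as.matrix(cognitive_loading)
  if (!all(dim(cognitive_loading) == c(8, 2)))
    stop("cognitive_loading must be 8 x 2")
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         n_rois = as.integer(n_rois), module_sizes = as.integer(module_sizes),
         within_coupling = within_coupling,
         between_coupling = between_coupling,
         inflection_age = inflection_age,
         cross_loading_sd = cross_loading_sd,
         ts_length = as.integer(ts_length), noise_sd = noise_sd,
         cognitive_noise_sd = cognitive_noise_sd,
         cognitive_loading = cognitive_loading,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default task loading matrix
#'
#' Loadings of the eight cognitive tasks on the (domain-general, semantic)
#' latent factors, ordered from synergy-heavy production tasks to
#' memory/comprehension tasks: naming, verbal fluency, proverb
#' comprehension, tip-of-the-tongue, hotel (multitasking), Cattell (fluid
#' intelligence), story recall, sentence comprehension.
#'
#' @return 8 x 2 numeric matrix with task rownames.
#' @export
default_task_loadings <- function() {
  m <- rbind(
    naming        = c(0.5, 0.5),
    fluency       = c(0.6, 0.3),
    proverb       = c(0.5, 0.5),
    tot           = c(0.5, 0.2),
    hotel         = c(0.7, 0.0),
    cattell       = c(0.7, -0.2),
    story_recall  = c(0.2, 0.5),
    sentence_comp = c(0.2, 0.6)
  )
  colnames(m) <- c("domain_general", "semantic")
  m
}

#' Planted module labels of a spec
#'
#' @param spec `cohort_spec`.
#' @return Integer vector of length `n_rois`: module ids 1..K, 0 for
#'   unassigned ROIs.
#' @export
planted_modules <- function(spec) {
  lab <- rep(0L, spec$n_rois)
  start <- 1L
  for (k in seq_along(spec$module_sizes)) {
    lab[start:(start + spec$module_sizes[k] - 1L)] <- k
    start <- start + spec$module_sizes[k]
  }
  names(lab) <- sprintf("roi_%03d", seq_len(spec$n_rois))
  lab
}

# Deterministic per-subject sub-seed from (master seed, index); stays below
# 2^31 so it is a valid R integer seed.
.sub_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 1000003 + index * 7919 + salt * 104729) %%
               2147483629)
}

#' Generate one synthetic connectome
#'
#' Simulates the block factor time-series model at a given age and returns
#' the Fisher-z correlation matrix. Module signals and the global signal are
#' independent standard Gaussian series; node i's series is
#' `within_coupling(age) * f_module(i) +
#' between_coupling(age) * (sum_k eta_ik f_k + g) + noise`,
#' where the `eta_ik` are node-specific half-normal cross-loadings (SD
#' `cross_loading_sd`) onto the other modules. With `between_coupling == 0`
#' all off-block coupling vanishes; with `noise_sd == 0` as well, the model
#' reduces to the exact factor limit (within-block correlations 1,
#' off-block 0). Unassigned ROIs carry only the global/cross terms plus
#' noise. Correlations are clamped to |r| <= 1 - 1e-7 before the Fisher
#' transform so noise-free blocks stay finite.
#'
#' @param spec `cohort_spec`.
#' @param age subject age (within the spec's range).
#' @param seed integer seed for this subject's series.
#' @param coupling_shift additive perturbation of the between coupling
#'   (subject-level mechanism; default 0).
#' @return A `conn_matrix` (Fisher-z, symmetric, zero diagonal).
#' @export
generate_connectome <- function(spec, age, seed, coupling_shift = 0) {
  if (age < spec$age_range[1] || age > spec$age_range[2])
    stop("age outside the spec's range")
  w <- spec$within_coupling(age)
  b <- spec$between_coupling(age) + coupling_shift
  if (w <= b)
    stop(sprintf("degenerate coupling at age %.1f: within (%.3f) <= between (%.3f)",
                 age, w, b))
  modules <- planted_modules(spec)
  tlen <- spec$ts_length
  n <- spec$n_rois
  .with_seed(seed, function() {
    k <- length(spec$module_sizes)
    fmod <- matrix(stats::rnorm(tlen * k), tlen, k)
    g <- stats::rnorm(tlen)
    eta <- spec$cross_loading_sd * matrix(abs(stats::rnorm(n * k)), n, k)
    ts <- matrix(0, tlen, n)
    for (i in seq_len(n)) {
      loads <- b * eta[i, ]
      if (modules[i] > 0) loads[modules[i]] <- w
      ts[, i] <- as.numeric(fmod %*% loads) + b * g +
        spec$noise_sd * stats::rnorm(tlen)
    }
    r <- suppressWarnings(stats::cor(ts))
    r[!is.finite(r)] <- 0        # constant series (noise_sd=0, unassigned, b=0)
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
    z <- atanh(r)
    diag(z) <- 0
    z <- (z + t(z)) / 2
    conn_matrix(z, roi_labels = names(modules), age = age)
  })
}

#' Generate one subject's cognitive scores
#'
#' Latent factors: domain-general declines linearly over the age range (from
#' +1 to -1); semantic follows an inverted U peaking at the spec's
#' inflection age. Subject-level mechanism shifts are added to the factors,
#' scores are `loadings %*% factors + noise`, and entries go missing
#' completely at random at `missing_rate`.
#'
#' @param spec `cohort_spec`.
#' @param mechanisms list with numeric elements `domain_general` and
#'   `semantic` (subject-level factor shifts; default 0/0).
#' @param age subject age.
#' @param seed integer seed.
#' @return Named numeric vector of 8 task scores (NA = missing), with the
#'   planted factor values in attribute `"latent"`.
#' @export
generate_cognition <- function(spec, mechanisms = list(domain_general = 0,
                                                       semantic = 0),
                               age, seed) {
  L <- spec$cognitive_loading
  a0 <- spec$age_range[1]; a1 <- spec$age_range[2]
  f1 <- 1 - 2 * (age - a0) / (a1 - a0) + mechanisms$domain_general
  peak <- spec$inflection_age
  f2 <- exp(-((age - peak)^2) / (2 * 15^2)) + mechanisms$semantic
  .with_seed(seed, function() {
    scores <- as.numeric(L %*% c(f1, f2)) +
      spec$cognitive_noise_sd * stats::rnorm(nrow(L))
    names(scores) <- rownames(L)
    if (spec$missing_rate > 0) {
      miss <- stats::runif(length(scores)) < spec$missing_rate
      scores[miss] <- NA_real_
    }
    attr(scores, "latent") <- c(domain_general = f1, semantic = f2)
    scores
  })
}

#' Synthetic ROI annotation table
#'
#' Maps each planted module to a dominant resting-state network (module 1 ->
#' DMN, 2 -> SMN, 3 -> CON, 4 -> FPN, unassigned -> VMM), with a minority of
#' ROIs per module drawing their primary RSN from the other networks, and
#' percent overlaps drawn uniformly in \[50, 100\]. Synthetic stand-in for a
#' voxel-overlap RSN labeling.
#'
#' @param spec `cohort_spec`.
#' @param seed integer seed (default: spec seed).
#' @return data.frame: `roi`, `primary_rsn`, `percent_overlap`.
#' @export
synthetic_roi_annotation <- function(spec, seed = spec$seed) {
  modules <- planted_modules(spec)
  rsn_main <- c("DMN", "SMN", "CON", "FPN")
  all_rsn <- c(rsn_main, "LANG", "DAN")
  .with_seed(.sub_seed(seed, 0L, salt = 3L), function() {
    rsn <- vapply(modules, function(m) {
      if (m == 0) return("VMM")
      if (stats::runif(1) < 0.7) rsn_main[m]
      else sample(setdiff(all_rsn, rsn_main[m]), 1)
    }, character(1))
    data.frame(
      roi = names(modules),
      primary_rsn = unname(rsn),
      percent_overlap = round(stats::runif(length(modules), 50, 100), 1),
      row.names = NULL
    )
  })
}

#' Demographics draw for a cohort spec
#'
#' The deterministic demographic table underlying [generate_cohort()]: ages
#' uniform (rounded to integer years) over the spec's range, balanced sex
#' codes, and total intracranial volumes around 1500 cm^3.
#'
#' @param spec `cohort_spec`.
#' @return data.frame with columns `age`, `sex`, `tiv` (one row per subject).
#' @export
cohort_demographics <- function(spec) {
  n <- spec$n_subjects
  .with_seed(spec$seed, function() {
    data.frame(
      age = round(stats::runif(n, spec$age_range[1], spec$age_range[2])),
      sex = stats::rbinom(n, 1, 0.5),
      tiv = pmax(stats::rnorm(n, 1500, 150), 900)
    )
  })
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly over the spec's range, simulates each subject's
#' connectome and cognitive scores from deterministic per-subject sub-seeds,
#' and (optionally) writes the standard on-disk layout: one
#' `<id>_matrix.tsv` per subject, `participants.tsv` (subject_id, age, sex,
#' tiv), `cognition.tsv` (empty cell = missing) and `roi_annotation.tsv`.
#' A shared subject-level coupling perturbation links the connectome's
#' between-module coupling to the domain-general cognitive factor (the
#' planted brain-cognition mechanism).
#'
#' @param spec `cohort_spec`.
#' @param out_dir directory to write the cohort layout into, or NULL to
#'   keep the cohort in memory only.
#' @return List of `synthetic_subject` lists (`subject_id`, `age`, `sex`,
#'   `tiv`, `matrix`, `scores`, `latent_truth`), with the annotation table
#'   as attribute `"roi_annotation"`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  n <- spec$n_subjects
  base <- cohort_demographics(spec)
  subjects <- lapply(seq_len(n), function(i) {
    sseed <- .sub_seed(spec$seed, i)
    mech <- .with_seed(.sub_seed(spec$seed, i, salt = 1L), function()
      list(domain_general = 0.3 * stats::rnorm(1),
           semantic = 0.3 * stats::rnorm(1)))
    # shared perturbation: stronger between-coupling <-> lower domain-general
    shift <- -0.05 * mech$domain_general
    cm <- generate_connectome(spec, base$age[i], sseed,
                              coupling_shift = shift)
    sc <- generate_cognition(spec, mech, base$age[i],
                             .sub_seed(spec$seed, i, salt = 2L))
    id <- sprintf("sub-%04d", i)
    cm$subject_id <- id; cm$sex <- base$sex[i]; cm$tiv <- base$tiv[i]
    list(subject_id = id, age = base$age[i], sex = base$sex[i],
         tiv = base$tiv[i], matrix = cm, scores = sc,
         latent_truth = list(modules = planted_modules(spec),
                             factors = attr(sc, "latent"),
                             mechanisms = mech,
                             coupling_shift = shift))
  })
  attr(subjects, "roi_annotation") <- synthetic_roi_annotation(spec)
  class(subjects) <- "synthetic_cohort"
  if (!is.null(out_dir)) write_cohort(subjects, out_dir)
  subjects
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  ages <- vapply(x, `[[`, numeric(1), "age")
  cat(sprintf("<synthetic_cohort> %d subjects, ages %d-%d, %d ROIs\n",
              length(x), min(ages), max(ages),
              nrow(x[[1]]$matrix$values)))
  invisible(x)
}

#' Write a cohort to the standard on-disk layout
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  participants <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               tiv = s$tiv)))
  utils::write.table(participants, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cog <- do.call(rbind, lapply(cohort, function(s)
    cbind(data.frame(subject_id = s$subject_id),
          as.data.frame(as.list(unclass(s$scores))))))
  utils::write.table(cog, file.path(out_dir, "cognition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(attr(cohort, "roi_annotation"),
                     file.path(out_dir, "roi_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in cohort) {
    m <- s$matrix$values
    df <- data.frame(roi = rownames(m), m, check.names = FALSE)
    utils::write.table(df,
                       file.path(out_dir,
                                 sprintf("%s_matrix.tsv", s$subject_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Read one connectivity matrix from the on-disk layout
#'
#' @param path path to a `<id>_matrix.tsv` file (first column = ROI labels,
#'   remaining columns the square matrix).
#' @return A `conn_matrix` (metadata unset).
#' @export
read_connectivity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  conn_matrix(m, roi_labels = df[[1]])
}

#' Read a cohort layout from disk
#'
#' @param dir directory written by [write_cohort()].
#' @return list: `participants`, `cognition`, `roi_annotation` data.frames
#'   and `matrices` (named list of `conn_matrix`).
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.delim(file.path(dir, "participants.tsv"))
  cognition <- utils::read.delim(file.path(dir, "cognition.tsv"))
  annotation <- utils::read.delim(file.path(dir, "roi_annotation.tsv"))
  matrices <- lapply(participants$subject_id, function(id) {
    cm <- read_connectivity_matrix(file.path(dir,
                                             sprintf("%s_matrix.tsv", id)))
    i <- match(id, participants$subject_id)
    cm$subject_id <- id
    cm$age <- participants$age[i]
    cm$sex <- participants$sex[i]
    cm$tiv <- participants$tiv[i]
    cm
  })
  names(matrices) <- participants$subject_id
  list(participants = participants, cognition = cognition,
       roi_annotation = annotation, matrices = matrices)
}

#' Simulate role compositions with planted age trends
#'
#' Direct generator for the compositional modeling stage: per subject, role
#' logits follow planted linear lifespan trends (total change over the age
#' range, on the log-odds scale) plus an optional Gaussian midlife bump and
#' noise, and are mapped through a softmax onto the 4-role simplex.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param age_range default c(18, 88).
#' @param intercepts baseline role logits (default approximates observed
#'   mean proportions ~ 30/26/24/19%).
#' @param slopes per-role total logit change from the start to the end of
#'   the age range (default: connector +0.5, provincial -0.8, satellite
#'   -0.2, peripheral +0.3).
#' @param bump_amplitude per-role amplitude of a Gaussian bump at
#'   `bump_age` (default all 0).
#' @param bump_age center of the bump (default 55).
#' @param bump_width SD of the bump in years (default 12).
#' @param noise_sd logit-scale noise SD (default 0.3).
#' @return list: `ages`, `compositions` (n x 4 matrix, rows sum to 1),
#'   `logits` (planted noise-free logits).
#' @export
simulate_role_compositions <- function(n, seed,
                                       age_range = c(18, 88),
                                       intercepts = c(connector = 0.2,
                                                      provincial = 0.1,
                                                      satellite = 0.0,
                                                      peripheral = -0.3),
                                       slopes = c(connector = 0.5,
                                                  provincial = -0.8,
                                                  satellite = -0.2,
                                                  peripheral = 0.3),
                                       bump_amplitude = c(0, 0, 0, 0),
                                       bump_age = 55, bump_width = 12,
                                       noise_sd = 0.3) {
  .with_seed(seed, function() {
    ages <- round(stats::runif(n, age_range[1], age_range[2]))
    a01 <- (ages - age_range[1]) / diff(age_range)
    bump <- exp(-((ages - bump_age)^2) / (2 * bump_width^2))
    logits <- sapply(seq_len(4), function(r)
      intercepts[r] + slopes[r] * a01 + bump_amplitude[r] * bump)
    noisy <- logits + matrix(stats::rnorm(n * 4, sd = noise_sd), n, 4)
    comp <- exp(noisy) / rowSums(exp(noisy))
    colnames(comp) <- colnames(logits) <- .role_levels
    list(ages = ages, compositions = comp, logits = logits)
  })
}

#' Simulate a role-label cohort from a frequency cube
#'
#' Draws per-subject, per-region role labels independently from the planted
#' group frequencies, with subjects spread over the three age groups —
#' ground truth for the trajectory model.
#'
#' @param cube `role_freq_cube`-shaped array `[region, group, role]` of
#'   planted frequencies (rows summing to 1 over roles).
#' @param n_per_group subjects per age group.
#' @param seed integer seed.
#' @return list: `role_matrix` (subjects x regions), `ages`.
#' @export
simulate_role_cohort <- function(cube, n_per_group, seed) {
  groups <- c("younger", "middle", "older")
  rep_ages <- c(younger = 30, middle = 50, older = 70)
  n_reg <- dim(cube)[1]
  .with_seed(seed, function() {
    rows <- list(); ages <- integer(0)
    for (g in groups) {
      for (s in seq_len(n_per_group)) {
        roles <- vapply(seq_len(n_reg), function(j)
          sample(.role_levels, 1, prob = cube[j, g, ]), character(1))
        rows[[length(rows) + 1]] <- roles
        ages <- c(ages, rep_ages[[g]])
      }
    }
    rm_ <- do.call(rbind, rows)
    colnames(rm_) <- dimnames(cube)[[1]]
    list(role_matrix = rm_, ages = ages)
  })
}

#' Simulate two variable sets sharing one latent factor
#'
#' Ground truth for canonical correlation recovery: latent scores `u` and
#' `v` with correlation `latent_r`; every X column loads on `u` and every Y
#' column on `v`, plus independent noise. With small column noise the first
#' canonical correlation approaches `latent_r`. `latent_r = 0` gives pure
#' noise.
#'
#' @param n subjects.
#' @param px,py columns per set (default 3 each).
#' @param latent_r planted latent correlation (default 0.6).
#' @param noise_sd column noise SD (default 0.3).
#' @param seed integer seed.
#' @return list: `X`, `Y`, `u`, `v`.
#' @export
simulate_cca_data <- function(n, px = 3, py = 3, latent_r = 0.6,
                              noise_sd = 0.3, seed = NULL) {
  .with_seed(seed, function() {
    u <- stats::rnorm(n)
    v <- latent_r * u + sqrt(1 - latent_r^2) * stats::rnorm(n)
    X <- sapply(seq_len(px), function(j) u + noise_sd * stats::rnorm(n))
    Y <- sapply(seq_len(py), function(j) v + noise_sd * stats::rnorm(n))
    colnames(X) <- sprintf("x%02d", seq_len(px))
    colnames(Y) <- sprintf("y%02d", seq_len(py))
    list(X = X, Y = Y, u = u, v = v)
  })
}
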