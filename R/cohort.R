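#' Default ground-truth cross-lagged matrix
#'
#' A sparse 24 x 24 matrix of standardized lagged effects used as the
#' simulator's default dynamics. The diagonal holds autoregressive effects
#' (PLEs factors are the most trait-stable, with PI the largest, so that the
#' screening classification shows realistic one-year persistence); the
#' off-diagonal part contains a small set of cross-construct effects of the
#' kind reported for college-student symptom networks (depression and anxiety
#' items feeding PLEs factors, adjustment stress feeding PI/BEs,
#' interpersonal stress feeding emotional symptoms).
#'
#' @return 24 x 24 numeric matrix with node-label dimnames.
#' @export
default_truth_matrix <- function() {
  info <- clpn_node_info()
  B <- matrix(0, 24, 24, dimnames = list(info$node, info$node))
  # autoregression: PLEs most stable, PI highest
  diag(B) <- c(0.42, 0.37, 0.34,            # PI, BEs, PAs
               rep(0.25, 9),                # PHQ items
               rep(0.25, 7),                # GAD items
               rep(0.20, 5))                # ASLEC factors
  edge <- function(from, to, w) B[from, to] <<- w
  edge("PHQ9", "PI", 0.20)    # suicide/self-harm -> persecutory ideation
  edge("GAD6", "PI", 0.17)    # irritability -> persecutory ideation
  edge("GAD5", "BEs", 0.11)   # restlessness -> bizarre experiences
  edge("PHQ8", "BEs", 0.20)   # psychomotor disturbance -> bizarre experiences
  edge("PHQ8", "PI", 0.10)
  edge("A3", "PI", 0.08)      # adjustment stress -> PI
  edge("A3", "BEs", 0.06)
  edge("A4", "PHQ7", 0.06)    # interpersonal stress -> concentration
  edge("A4", "GAD3", 0.06)
  edge("PI", "PHQ2", 0.10); edge("PI", "GAD2", 0.10)
  edge("BEs", "PHQ6", 0.08)
  edge("PHQ1", "PHQ2", 0.12); edge("PHQ2", "PHQ1", 0.12)
  edge("PHQ4", "PHQ3", 0.10); edge("PHQ5", "PHQ4", 0.08)
  edge("GAD1", "GAD2", 0.12); edge("GAD2", "GAD1", 0.10)
  edge("GAD7", "GAD6", 0.08); edge("GAD4", "GAD1", 0.08)
  edge("PHQ2", "GAD1", 0.10); edge("GAD1", "PHQ1", 0.10)
  edge("A1", "A2", 0.08); edge("A5", "A3", 0.08); edge("A4", "A3", 0.08)
  edge("A2", "PHQ1", 0.06); edge("A5", "GAD3", 0.06)
  edge("PHQ3", "GAD5", 0.08); edge("GAD3", "PHQ6", 0.08)
  B
}

#' Random sparse ground-truth matrix
#'
#' Draws a seeded sparse cross-lagged matrix for recovery experiments:
#' `n_edges` off-diagonal effects with magnitudes uniform in `beta_range`
#' (mostly positive; a `neg_prob` share negative) and a constant
#' autoregressive diagonal.
#'
#' @param seed integer seed.
#' @param n_edges number of nonzero cross-lagged effects (default 30).
#' @param beta_range magnitude range (default `c(0.15, 0.35)`).
#' @param ar autoregressive coefficient placed on the diagonal.
#' @param neg_prob probability an effect is negative (default 0.2).
#' @return 24 x 24 matrix with node-label dimnames.
#' @export
random_truth_matrix <- function(seed, n_edges = 30L,
                                beta_range = c(0.15, 0.35), ar = 0.3,
                                neg_prob = 0.2) {
  info <- clpn_node_info()
  withr::with_seed(seed, {
    B <- matrix(0, 24, 24, dimnames = list(info$node, info$node))
    diag(B) <- ar
    off <- which(row(B) != col(B))
    idx <- sample(off, n_edges)
    B[idx] <- sample(c(-1, 1), n_edges, replace = TRUE,
                     prob = c(neg_prob, 1 - neg_prob)) *
      runif(n_edges, beta_range[1], beta_range[2])
    B
  })
}

#' Default wave-1 latent covariance
#'
#' Block-exchangeable covariance for the 24 latent node scores: unit
#' variances, within-construct correlation `r_within`, between-construct
#' correlation `r_between`. Positive definite for the defaults.
#'
#' @param r_within,r_between correlations (defaults 0.40 / 0.15).
#' @return 24 x 24 covariance matrix with node-label dimnames.
#' @export
default_wave1_covariance <- function(r_within = 0.40, r_between = 0.15) {
  info <- clpn_node_info()
  same <- outer(info$construct, info$construct, "==")
  S <- ifelse(same, r_within, r_between)
  diag(S) <- 1
  dimnames(S) <- list(info$node, info$node)
  S
}

#' Default covariate effects on wave-2 latents
#'
#' Named list mapping covariate design columns to length-24 vectors of
#' additive effects on the wave-2 latent node scores. Defaults: a history of
#' mental disorders raises PLEs and emotional-symptom latents; male sex has a
#' small effect on emotional symptoms only.
#'
#' @return named list of length-24 numeric vectors.
#' @export
default_covariate_effects <- function() {
  list(
    mental_history = rep(c(0.30, 0.20, 0.15, 0), c(3, 9, 7, 5)),
    sex_male = rep(c(0, 0.10, 0.12, 0), c(3, 9, 7, 5))
  )
}

#' Simulation configuration for a synthetic two-wave cohort
#'
#' Defines the study conditions the simulator reproduces: cohort size, the
#' ground-truth cross-lagged matrix, the wave-1 latent covariance, noise
#' levels, covariate effects, screening-prevalence targets, and the rates of
#' administrative artifacts (duplicates, speeders, psychotic-history flags,
#' refusals, follow-up loss). Defaults emulate a freshman cohort of 3,755
#' unique respondents with a 13.5% baseline positive-screen rate at the 1.57
#' weighted-score cut-off and the canonical exclusion ledger.
#'
#' @param n_participants number of unique participants (default 3755).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @param truth_matrix 24 x 24 standardized lagged-effect matrix (diagonal =
#'   autoregression).
#' @param wave1_covariance 24 x 24 symmetric positive-definite latent
#'   covariance.
#' @param noise_sd wave-2 latent disturbance SD, scalar or length 24
#'   (>= 0).
#' @param item_noise_sd item-level measurement noise SD.
#' @param discretize round and clip item responses to the Likert scale
#'   (`FALSE` yields continuous items, useful for moment checks).
#' @param covariate_effects named list, covariate design column -> length-24
#'   effect vector (scalars recycled).
#' @param prevalence_target baseline positive-screen fraction in (0, 1), or
#'   `NA` to skip calibration.
#' @param wave2_prevalence_target wave-2 positive fraction, or `NA`.
#' @param cutoff CAPE weighted-score cut-off used for calibration.
#' @param artifact_rates named list of fractions: `duplicates`, `speeders`,
#'   `psychotic_history`, `refusals`, `followup_loss` (all in `[0, 1]`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 3755L,
                       seed = 1L,
                       truth_matrix = default_truth_matrix(),
                       wave1_covariance = default_wave1_covariance(),
                       noise_sd = 0.8,
                       item_noise_sd = 0.6,
                       discretize = TRUE,
                       covariate_effects = default_covariate_effects(),
                       prevalence_target = 0.135,
                       wave2_prevalence_target = 0.0718,
                       cutoff = 1.57,
                       artifact_rates = list(duplicates = 111 / 3755,
                                             speeders = 2 / 3755,
                                             psychotic_history = 14 / 3755,
                                             refusals = 11 / 3755,
                                             followup_loss = 370 / 3728)) {
  cfg <- structure(list(n_participants = as.integer(n_participants),
                        seed = as.integer(seed),
                        truth_matrix = truth_matrix,
                        wave1_covariance = wave1_covariance,
                        noise_sd = noise_sd,
                        item_noise_sd = item_noise_sd,
                        discretize = isTRUE(discretize),
                        covariate_effects = covariate_effects,
                        prevalence_target = prevalence_target,
                        wave2_prevalence_target = wave2_prevalence_target,
                        cutoff = cutoff,
                        artifact_rates = artifact_rates),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- nrow(clpn_node_info())
  if (!is.matrix(cfg$truth_matrix) || !all(dim(cfg$truth_matrix) == p))
    fail("sim_config: truth_matrix must be %d x %d", p, p)
  S <- cfg$wave1_covariance
  if (!is.matrix(S) || !all(dim(S) == p))
    fail("sim_config: wave1_covariance must be %d x %d", p, p)
  if (!isSymmetric(unname(S), tol = 1e-8))
    fail("sim_config: wave1_covariance is not symmetric")
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    fail("sim_config: wave1_covariance is not positive definite")
  if (any(cfg$noise_sd < 0) || !(length(cfg$noise_sd) %in% c(1L, p)))
    fail("sim_config: noise_sd must be >= 0, length 1 or %d", p)
  rates <- unlist(cfg$artifact_rates)
  if (any(rates < 0 | rates > 1))
    fail("sim_config: artifact rates must lie in [0, 1]")
  for (tg in c("prevalence_target", "wave2_prevalence_target")) {
    v <- cfg[[tg]]
    if (!is.na(v) && (v <= 0 || v >= 1))
      fail("sim_config: %s must lie in (0, 1)", tg)
  }
  invisible(cfg)
}

# Likert anchor (latent 0 maps near this response value) per instrument.
item_centers <- function() c(cape = 1.35, phq = 1.60, gad = 1.60, aslec = 1.90)

# Build item responses for one factor-structured instrument.
# z: n-vector of latent factor scores; e: n x k item noise; returns n x k.
make_items <- function(z, e, center, smin, smax, discretize) {
  raw <- center + z + e
  if (discretize) pmin(pmax(round(raw), smin), smax) else raw
}

# Realized screen-positive fraction of the CAPE weighted score when the
# three PLEs latents are shifted by delta (item noise held fixed).
cape_prevalence_at <- function(delta, zp, e_cape, spec, discretize) {
  centers <- item_centers()
  k <- vapply(spec$factors, length, 1L)
  items <- mapply(function(f, cols) {
    make_items(zp[, f] + delta, e_cape[, cols, drop = FALSE],
               centers["cape"], spec$scale_min, spec$scale_max, discretize)
  }, seq_along(spec$factors),
     split(seq_len(15), rep(seq_along(k), k)),
     SIMPLIFY = FALSE)
  score <- rowMeans(do.call(cbind, items))
  function(cutoff) mean(score >= cutoff)
}

# Bisection on the PLEs latent mean shift so the realized screen-positive
# fraction hits the target; item-noise draws are held fixed, so the realized
# fraction is monotone non-decreasing in the shift.
calibrate_shift <- function(target, cutoff, zp, e_cape, spec, discretize,
                            wave_label) {
  prev_at <- function(d)
    cape_prevalence_at(d, zp, e_cape, spec, discretize)(cutoff)
  lo <- -4; hi <- 4
  p_lo <- prev_at(lo); p_hi <- prev_at(hi)
  if (target < p_lo || target > p_hi)
    fail("prevalence target %.3f for %s is outside the achievable range [%.3f, %.3f] of the latent distribution",
         target, wave_label, p_lo, p_hi)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (prev_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic two-wave cohort with known cross-lagged structure
#'
#' Wave-1 latent node scores are drawn from the configured covariance;
#' wave-2 latents are `Z1 %*% truth_matrix + covariate effects + Gaussian
#' noise`. Item responses are produced per node by adding item-level noise
#' and (by default) rounding and clipping to the instrument's Likert range.
#' The latent mean of the three PLEs factors is shifted by a
#' simulation-calibrated amount so the realized screen-positive fraction at
#' the weighted-score cut-off matches the configured prevalence targets
#' (wave 1, and after the lagged dynamics, wave 2). The same config and seed
#' always give bit-identical output.
#'
#' Administrative artifacts (duplicates, speeders, flags, follow-up loss)
#' are NOT present in the returned data; add them with
#' [inject_admin_artifacts()].
#'
#' @param config a [sim_config()].
#' @return list with `data` (panel data.frame, one row per participant per
#'   wave) and `truth` (class `clpn_ground_truth`: the truth matrix, realized
#'   prevalences, calibrated shifts, seed and generation parameters).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 300, seed = 7))
#' dim(cohort$data)
#' cohort$truth$realized_prevalence
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  info <- clpn_node_info()
  p <- nrow(info)
  instruments <- default_instruments()
  centers <- item_centers()

  withr::with_seed(config$seed, {
    n <- config$n_participants
    covars <- data.frame(
      id = seq_len(n),
      age = sample(17:22, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      ethnicity_minority = rbinom(n, 1, 0.08),
      birth_rural = rbinom(n, 1, 0.30),
      chronic_condition = rbinom(n, 1, 0.10),
      mental_history = rbinom(n, 1, 0.06),
      family_history = rbinom(n, 1, 0.05),
      stringsAsFactors = FALSE
    )

    Z1 <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = config$wave1_covariance)
    colnames(Z1) <- info$node

    # item-level measurement noise, drawn once so calibration is deterministic
    noise_block <- function(k) matrix(rnorm(n * k, sd = config$item_noise_sd), n, k)
    e1 <- list(cape = noise_block(15), phq = noise_block(9),
               gad = noise_block(7), aslec = noise_block(27))
    e2 <- list(cape = noise_block(15), phq = noise_block(9),
               gad = noise_block(7), aslec = noise_block(27))

    delta1 <- 0
    if (!is.na(config$prevalence_target))
      delta1 <- calibrate_shift(config$prevalence_target, config$cutoff,
                                Z1[, 1:3, drop = FALSE], e1$cape,
                                instruments$cape, config$discretize, "wave 1")
    Z1[, 1:3] <- Z1[, 1:3] + delta1

    # covariate design for the latent dynamics
    Xc <- cbind(age_c = covars$age - mean(17:22),
                sex_male = as.numeric(covars$sex == "male"),
                ethnicity_minority = covars$ethnicity_minority,
                birth_rural = covars$birth_rural,
                chronic_condition = covars$chronic_condition,
                mental_history = covars$mental_history,
                family_history = covars$family_history)
    G <- matrix(0, ncol(Xc), p, dimnames = list(colnames(Xc), info$node))
    for (nm in names(config$covariate_effects)) {
      if (!nm %in% rownames(G))
        fail("covariate_effects names an unknown covariate: %s", nm)
      G[nm, ] <- rep(config$covariate_effects[[nm]], length.out = p)
    }
    noise_sd <- rep(config$noise_sd, length.out = p)
    eps <- sweep(matrix(rnorm(n * p), n, p), 2, noise_sd, "*")
    Z2 <- Z1 %*% config$truth_matrix + Xc %*% G + eps

    delta2 <- 0
    if (!is.na(config$wave2_prevalence_target))
      delta2 <- calibrate_shift(config$wave2_prevalence_target, config$cutoff,
                                Z2[, 1:3, drop = FALSE], e2$cape,
                                instruments$cape, config$discretize, "wave 2")
    Z2[, 1:3] <- Z2[, 1:3] + delta2

    build_wave <- function(Z, e) {
      blocks <- list()
      for (key in c("cape", "phq", "gad", "aslec")) {
        spec <- instruments[[key]]
        if (is.null(spec$factors)) {
          # item-level nodes: one item per node (PHQ -> nodes 4:12, GAD -> 13:19)
          offset <- if (key == "phq") 3L else 12L
          nodes <- info$node[offset + seq_along(spec$items)]
          m <- matrix(0, n, length(spec$items))
          for (j in seq_along(spec$items))
            m[, j] <- make_items(Z[, nodes[j]], e[[key]][, j, drop = FALSE],
                                 centers[[key]], spec$scale_min,
                                 spec$scale_max, config$discretize)
        } else {
          k <- vapply(spec$factors, length, 1L)
          cols <- split(seq_along(spec$items), rep(seq_along(k), k))
          m <- matrix(0, n, length(spec$items))
          for (f in seq_along(spec$factors))
            m[, cols[[f]]] <- make_items(Z[, names(spec$factors)[f]],
                                         e[[key]][, cols[[f]], drop = FALSE],
                                         centers[[key]], spec$scale_min,
                                         spec$scale_max, config$discretize)
        }
        colnames(m) <- spec$items
        blocks[[key]] <- m
      }
      do.call(cbind, blocks)
    }
    items1 <- build_wave(Z1, e1)
    items2 <- build_wave(Z2, e2)

    base_ts <- as.numeric(as.POSIXct("2021-10-01 08:00:00", tz = "UTC"))
    admin1 <- data.frame(
      timestamp = round(base_ts + runif(n, 0, 14 * 86400)),
      response_time_seconds = pmax(320, round(rlnorm(n, log(900), 0.35))))
    admin2 <- data.frame(
      timestamp = round(base_ts + 365 * 86400 + runif(n, 0, 14 * 86400)),
      response_time_seconds = pmax(320, round(rlnorm(n, log(900), 0.35))))

    assemble <- function(wave, admin, items) {
      cbind(data.frame(id = covars$id, wave = wave,
                       timestamp = admin$timestamp,
                       response_time_seconds = admin$response_time_seconds),
            covars[, -1, drop = FALSE],
            data.frame(psychotic_history = 0L, refused = 0L),
            as.data.frame(items))
    }
    data <- rbind(assemble(1L, admin1, items1), assemble(2L, admin2, items2))
    rownames(data) <- NULL

    w1_score <- cape_weighted_score(items1[, instruments$cape$items])
    w2_score <- cape_weighted_score(items2[, instruments$cape$items])

    truth <- structure(list(
      truth_matrix = config$truth_matrix,
      realized_prevalence = mean(w1_score >= config$cutoff),
      realized_wave2_prevalence = mean(w2_score >= config$cutoff),
      shift = c(wave1 = delta1, wave2 = delta2),
      seed = config$seed,
      config = config
    ), class = "clpn_ground_truth")

    if (!is.na(config$prevalence_target) && n >= 2000 &&
        abs(truth$realized_prevalence - config$prevalence_target) > 0.02)
      fail("prevalence calibration missed the target by more than 2 percentage points (target %.3f, realized %.3f)",
           config$prevalence_target, truth$realized_prevalence)

    list(data = data, truth = truth)
  })
}

#' @export
print.clpn_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<clpn_ground_truth> seed %d, %d nonzero cross-lagged ",
                     "effects, realized prevalence %.3f (wave 2: %.3f)\n"),
              x$seed,
              sum(x$truth_matrix[row(x$truth_matrix) != col(x$truth_matrix)] != 0),
              x$realized_prevalence, x$realized_wave2_prevalence))
  invisible(x)
}

#' Inject administrative artifacts into a clean cohort
#'
#' Adds, at the configured rates (converted to exact counts by rounding):
#' duplicate wave-1 records with later timestamps, wave-1 response times
#' under five minutes ("speeders"), psychotic-history and refusal flags, and
#' follow-up loss (deleted wave-2 records). Speeders, flagged participants
#' and follow-up losses are disjoint sets, and follow-up loss is applied only
#' to participants not otherwise flagged, so the cohort-flow arithmetic is
#' exact. All counts are recorded in the `artifact_counts` attribute.
#'
#' @param data a panel data.frame from [generate_cohort()].
#' @param config the [sim_config()] holding `artifact_rates` and `seed`.
#' @return the modified data.frame with attribute `artifact_counts`.
#' @export
inject_admin_artifacts <- function(data, config) {
  rates <- config$artifact_rates
  bad <- unlist(rates) < 0 | unlist(rates) > 1
  if (any(bad)) fail("artifact rates must lie in [0, 1]")
  ids <- unique(data$id[data$wave == 1])
  n <- length(ids)
  n_dup <- round((rates$duplicates %||% 0) * n)
  n_speed <- round((rates$speeders %||% 0) * n)
  n_hist <- round((rates$psychotic_history %||% 0) * n)
  n_ref <- round((rates$refusals %||% 0) * n)
  n_surv <- n - n_speed - n_hist - n_ref
  n_loss <- round((rates$followup_loss %||% 0) * n_surv)
  if (n_speed + n_hist + n_ref + n_loss > n)
    fail("artifact rates flag more participants than exist")

  counts <- list(duplicates = n_dup, speeders = n_speed,
                 psychotic_history = n_hist, refusals = n_ref,
                 followup_loss = n_loss)
  if (all(unlist(counts) == 0)) {
    attr(data, "artifact_counts") <- counts
    return(data)
  }

  withr::with_seed(derive_seed(config$seed, "artifacts"), {
    flagged <- sample(ids, n_speed + n_hist + n_ref + n_loss)
    speed_ids <- flagged[seq_len(n_speed)]
    hist_ids <- flagged[n_speed + seq_len(n_hist)]
    ref_ids <- flagged[n_speed + n_hist + seq_len(n_ref)]
    loss_ids <- flagged[n_speed + n_hist + n_ref + seq_len(n_loss)]
    # duplicates never copy a speeder row, so speeder counts stay exact
    dup_ids <- sample(setdiff(ids, speed_ids), n_dup)

    out <- data
    if (n_speed > 0) {
      i <- which(out$wave == 1 & out$id %in% speed_ids)
      out$response_time_seconds[i] <- sample(60:299, length(i), replace = TRUE)
    }
    out$psychotic_history[out$id %in% hist_ids] <- 1L
    out$refused[out$id %in% ref_ids] <- 1L
    if (n_loss > 0)
      out <- out[!(out$wave == 2 & out$id %in% loss_ids), , drop = FALSE]
    if (n_dup > 0) {
      dup_rows <- out[out$wave == 1 & out$id %in% dup_ids, , drop = FALSE]
      dup_rows$timestamp <- dup_rows$timestamp +
        round(runif(nrow(dup_rows), 3600, 72 * 3600))
      out <- rbind(out, dup_rows)
    }
    rownames(out) <- NULL
    attr(out, "artifact_counts") <- counts
    out
  })
}

#' Export / re-import ground truth
#'
#' Writes the truth matrix as delimited text (full `%.17g` precision, so the
#' round trip is lossless) and the generation parameters as a JSON sidecar
#' at `<path>.json`.
#'
#' @param truth a `clpn_ground_truth` object.
#' @param path CSV path for the matrix.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  ok <- tryCatch({
    m <- truth$truth_matrix
    txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                  dimnames = dimnames(m))
    write.csv(txt, path, quote = FALSE, row.names = TRUE)
    sidecar <- list(
      seed = truth$seed,
      realized_prevalence = truth$realized_prevalence,
      realized_wave2_prevalence = truth$realized_wave2_prevalence,
      shift = as.list(truth$shift),
      n_participants = truth$config$n_participants,
      noise_sd = truth$config$noise_sd,
      item_noise_sd = truth$config$item_noise_sd,
      discretize = truth$config$discretize,
      prevalence_target = truth$config$prevalence_target,
      wave2_prevalence_target = truth$config$wave2_prevalence_target,
      cutoff = truth$config$cutoff,
      artifact_rates = truth$config$artifact_rates)
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    fail("export_truth: failed writing '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(truth_matrix = m,
                 realized_prevalence = side$realized_prevalence,
                 realized_wave2_prevalence = side$realized_wave2_prevalence,
                 shift = unlist(side$shift),
                 seed = side$seed,
                 config = side),
            class = "clpn_ground_truth")
}
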