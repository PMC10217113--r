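#' Semi-Markov specification for synthetic TDS trials
#'
#' Synthetic trials are generated by a semi-Markov chain on the attribute
#' set: states are attributes, the time spent in a state follows an
#' explicit sojourn distribution (gamma or lognormal, parameterized by
#' mean and standard deviation in seconds), and transitions follow a
#' stochastic matrix with zero diagonal (a panelist cannot "switch" to
#' the already-selected button). Temporal structure of the kind seen in
#' real TDS curves — different attributes prominent early, mid and late —
#' is produced by an optional phase schedule: separate transition
#' matrices for the early, middle and late thirds of the elapsed task
#' time. A time-homogeneous chain cannot produce a mid-task peak, which
#' is why the phase schedule exists.
#'
#' @param lexicon A [tds_lexicon()] of `q` attributes.
#' @param initial Probability vector of length `q` for the first
#'   selection.
#' @param transition `q x q` stochastic matrix, zero diagonal (ignored
#'   when `phase_transitions` is given; may then be `NULL`).
#' @param sojourn_mean,sojourn_sd Per-attribute sojourn mean/sd in
#'   seconds (length `q` or scalars, recycled).
#' @param sojourn_family `"gamma"` (default) or `"lognormal"`.
#' @param duration_mean,duration_sd Task duration distribution (gamma) in
#'   seconds.
#' @param phase_transitions Optional list of three `q x q` matrices
#'   (early/middle/late thirds of the task).
#' @param leadin_mean,leadin_sd Duration (seconds, gamma) of the `"none"`
#'   interval before the first press; `leadin_mean = 0` starts at the
#'   first instant.
#' @return A list of class `"tds_sm_spec"`.
#' @seealso [strawberry_spec()] for a ready-made 8-attribute preset,
#'   [simulate_trial()], [simulate_panel()].
#' @export
semi_markov_spec <- function(lexicon, initial, transition = NULL,
                             sojourn_mean = 3, sojourn_sd = 1.5,
                             sojourn_family = c("gamma", "lognormal"),
                             duration_mean = 30, duration_sd = 5,
                             phase_transitions = NULL,
                             leadin_mean = 0, leadin_sd = 0) {
  lexicon <- as_tds_lexicon(lexicon)
  q <- length(lexicon)
  sojourn_family <- match.arg(sojourn_family)
  initial <- as.numeric(initial)
  if (length(initial) != q || any(initial < 0) || abs(sum(initial) - 1) > 1e-8) {
    abort("`initial` must be a length-q probability vector.",
      class = "tdsim_error_spec"
    )
  }
  check_T <- function(T, what) {
    T <- as.matrix(T)
    if (!identical(dim(T), c(q, q))) {
      abort(sprintf("%s must be %d x %d.", what, q, q), class = "tdsim_error_spec")
    }
    if (q > 1L) {
      if (any(diag(T) != 0)) {
        abort(sprintf("%s must have a zero diagonal.", what),
          class = "tdsim_error_spec"
        )
      }
      bad <- which(abs(rowSums(T) - 1) > 1e-8 | apply(T, 1L, function(r) any(r < 0)))
      if (length(bad)) {
        abort(sprintf(
          "%s row(s) %s must be non-negative and sum to 1.",
          what, paste(bad, collapse = ", ")
        ), class = "tdsim_error_spec")
      }
    }
    T
  }
  if (is.null(phase_transitions)) {
    if (is.null(transition)) {
      abort("Give `transition` or `phase_transitions`.", class = "tdsim_error_spec")
    }
    phase_transitions <- rep(list(check_T(transition, "`transition`")), 3L)
  } else {
    if (length(phase_transitions) != 3L) {
      abort("`phase_transitions` must list 3 matrices (early/middle/late).",
        class = "tdsim_error_spec"
      )
    }
    phase_transitions <- lapply(seq_len(3L), function(i) {
      check_T(phase_transitions[[i]], sprintf("`phase_transitions[[%d]]`", i))
    })
    if (is.null(transition)) transition <- phase_transitions[[2L]]
  }
  recycle_q <- function(x, name) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, q)
    if (length(x) != q || any(x < 0) || any(is.na(x))) {
      abort(sprintf("`%s` must be %d non-negative value(s).", name, q),
        class = "tdsim_error_spec"
      )
    }
    x
  }
  sojourn_mean <- recycle_q(sojourn_mean, "sojourn_mean")
  sojourn_sd <- recycle_q(sojourn_sd, "sojourn_sd")
  if (any(sojourn_mean <= 0)) {
    abort("Sojourn means must be positive.", class = "tdsim_error_spec")
  }
  stopifnot_scalar_number(duration_mean, "duration_mean", positive = TRUE)
  stopifnot_scalar_number(duration_sd, "duration_sd")
  stopifnot_scalar_number(leadin_mean, "leadin_mean")
  stopifnot_scalar_number(leadin_sd, "leadin_sd")
  structure(
    list(
      lexicon = lexicon, q = q, initial = initial,
      phase_transitions = phase_transitions,
      sojourn_family = sojourn_family,
      sojourn_mean = sojourn_mean, sojourn_sd = sojourn_sd,
      duration_mean = duration_mean, duration_sd = duration_sd,
      leadin_mean = leadin_mean, leadin_sd = leadin_sd
    ),
    class = "tds_sm_spec"
  )
}

#' @export
print.tds_sm_spec <- function(x, ...) {
  cat(sprintf(
    "<tds_sm_spec> q = %d (%s), sojourn %s, duration %g +/- %g s\n",
    x$q, paste(unclass(x$lexicon), collapse = ", "),
    x$sojourn_family, x$duration_mean, x$duration_sd
  ))
  invisible(x)
}

draw_positive <- function(n, mean, sd, family = "gamma") {
  if (sd == 0 || mean == 0) {
    return(rep(mean, n))
  }
  if (family == "gamma") {
    shape <- (mean / sd)^2
    rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sdlog <- sqrt(log1p((sd / mean)^2))
    rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Simulate a single TDS trial
#'
#' Draws a task duration, an optional `"none"` lead-in, an initial
#' attribute, and then alternates sojourn draws with phase-conditioned
#' transitions until the duration budget is exhausted; the final sojourn
#' is truncated at the stop time. Output is deterministic given the seed
#' and no global random state is touched.
#'
#' @param spec A [semi_markov_spec()].
#' @param seed Integer seed (mandatory; no global RNG state is used).
#' @param trial_id,panel_id,replicate Trial identity.
#' @return A one-trial [tds_trialset()].
#' @export
simulate_trial <- function(spec, seed, trial_id = "T1", panel_id = trial_id,
                           replicate = 1L) {
  if (!inherits(spec, "tds_sm_spec")) {
    abort("`spec` must come from semi_markov_spec().", class = "tdsim_error_spec")
  }
  with_seed(seed, {
    D <- draw_positive(1L, spec$duration_mean, spec$duration_sd)
    D <- max(D, 1e-3)
    t0 <- if (spec$leadin_mean > 0) {
      draw_positive(1L, spec$leadin_mean, spec$leadin_sd)
    } else {
      0
    }
    att <- integer(0)
    tim <- numeric(0)
    if (t0 < D) {
      state <- sample.int(spec$q, 1L, prob = spec$initial)
      t <- t0
      repeat {
        att <- c(att, state)
        tim <- c(tim, t)
        t <- t + draw_positive(
          1L, spec$sojourn_mean[state], spec$sojourn_sd[state],
          spec$sojourn_family
        )
        if (t >= D || spec$q == 1L) break
        phase <- min(floor(3 * t / D) + 1L, 3L)
        state <- sample.int(spec$q, 1L, prob = spec$phase_transitions[[phase]][state, ])
      }
    }
    ev <- if (length(att)) {
      tibble(attribute = as.character(spec$lexicon)[att], time = tim)
    } else {
      NULL
    }
    tds_trial(ev, 0, D, trial_id, panel_id, replicate, spec$lexicon)
  })
}

#' Simulate a full panel of TDS trials
#'
#' `n_panels * replicates` independent trials with ids in the
#' letter-plus-digit convention (`"A1"` is panel A's first replicate).
#' Child seeds are derived deterministically from the master seed, so the
#' whole panel is reproducible.
#'
#' @inheritParams simulate_trial
#' @param n_panels,replicates Panel and replicate counts (defaults 17 and
#'   3, i.e. 51 trials).
#' @param panel_effect_sd Optional between-panelist heterogeneity: the
#'   log-standard-deviation of a multiplicative lognormal random effect
#'   on each panelist's sojourn means. Default 0 (homogeneous panel).
#' @return A [tds_trialset()].
#' @examples
#' panel <- simulate_panel(strawberry_spec(), seed = 1)
#' n_trials(panel) # 51
#' @export
simulate_panel <- function(spec, seed, n_panels = 17L, replicates = 3L,
                           panel_effect_sd = 0) {
  if (n_panels < 1L || replicates < 1L) {
    abort("`n_panels` and `replicates` must be >= 1.", class = "tdsim_error_domain")
  }
  stopifnot_scalar_number(panel_effect_sd, "panel_effect_sd")
  panel_names <- if (n_panels <= 26L) {
    LETTERS[seq_len(n_panels)]
  } else {
    sprintf("P%02d", seq_len(n_panels))
  }
  seeds <- child_seeds(seed, n_panels * replicates + 1L)
  panel_scale <- if (panel_effect_sd > 0) {
    with_seed(seeds[n_panels * replicates + 1L], {
      exp(stats::rnorm(n_panels, -panel_effect_sd^2 / 2, panel_effect_sd))
    })
  } else {
    rep(1, n_panels)
  }
  k <- 0L
  sets <- vector("list", n_panels * replicates)
  for (p in seq_len(n_panels)) {
    pspec <- spec
    pspec$sojourn_mean <- spec$sojourn_mean * panel_scale[p]
    for (rep in seq_len(replicates)) {
      k <- k + 1L
      sets[[k]] <- simulate_trial(
        pspec, seeds[k],
        trial_id = paste0(panel_names[p], rep),
        panel_id = panel_names[p], replicate = rep
      )
    }
  }
  tds_trialset(dplyr::bind_rows(lapply(sets, as_tibble)), spec$lexicon)
}

#' Replace one trial with a planted outlier archetype
#'
#' Injects one of three behaviorally motivated outlier archetypes,
#' leaving every other trial untouched:
#' * `"single_attribute"`: the panelist holds one button for the whole
#'   task — dominance durations collapse onto a single attribute, which
#'   stands out already at `R = 1`.
#' * `"rare_attributes"`: the panelist dwells on the attributes the rest
#'   of the panel selects least (computed from the spec's transition
#'   weights), at every phase of the task.
#' * `"time_shifted"`: the trial's own step function reversed in time —
#'   whole-trial durations are unchanged (invisible at `R = 1`) but the
#'   timing is maximally wrong (conspicuous at large `R`).
#'
#' @param trials A [tds_trialset()].
#' @param archetype One of `"single_attribute"`, `"rare_attributes"`,
#'   `"time_shifted"`.
#' @param target_id The trial to replace.
#' @param attribute For `"single_attribute"`: the attribute held.
#' @param spec For `"rare_attributes"`: the [semi_markov_spec()] the
#'   panel was generated from.
#' @param seed Seed for archetypes that draw randomness.
#' @return A [tds_trialset()] with the target replaced.
#' @export
inject_outlier <- function(trials, archetype = c(
                             "single_attribute", "rare_attributes",
                             "time_shifted"
                           ),
                           target_id, attribute = NULL, spec = NULL,
                           seed = 1L) {
  archetype <- match.arg(archetype)
  if (!target_id %in% trial_ids(trials)) {
    abort(sprintf("Unknown target trial '%s'.", target_id),
      class = "tdsim_error_validation"
    )
  }
  ev <- as_tibble(trials)
  target <- ev[ev$trial_id == target_id, ]
  others <- ev[ev$trial_id != target_id, ]
  meta <- list(
    panel_id = target$panel_id[1L], replicate = target$replicate[1L],
    duration_seconds = target$duration_seconds[1L]
  )
  new_rows <- switch(archetype,
    single_attribute = {
      if (is.null(attribute)) {
        abort("`attribute` is required for the single_attribute archetype.",
          class = "tdsim_error_domain"
        )
      }
      check_attributes(attribute, lexicon(trials))
      tibble(
        trial_id = target_id, panel_id = meta$panel_id,
        replicate = meta$replicate, attribute = attribute, onset = 0,
        duration_seconds = meta$duration_seconds
      )
    },
    rare_attributes = {
      if (is.null(spec)) {
        abort("`spec` is required for the rare_attributes archetype.",
          class = "tdsim_error_domain"
        )
      }
      if (spec$q < 2L) {
        abort("rare_attributes needs q >= 2.", class = "tdsim_error_domain")
      }
      # attributes least likely to be entered, averaged over phases
      w <- Reduce(`+`, lapply(spec$phase_transitions, colMeans)) / 3 +
        spec$initial
      n_rare <- max(2L, ceiling(spec$q / 4))
      rare <- order(w)[seq_len(n_rare)]
      sub_T <- matrix(1 / (n_rare - 1), n_rare, n_rare)
      diag(sub_T) <- 0
      sub <- semi_markov_spec(
        tds_lexicon(as.character(spec$lexicon)[rare]),
        initial = rep(1 / n_rare, n_rare), transition = sub_T,
        sojourn_mean = spec$sojourn_mean[rare],
        sojourn_sd = spec$sojourn_sd[rare],
        sojourn_family = spec$sojourn_family,
        duration_mean = if (is.na(meta$duration_seconds)) {
          spec$duration_mean
        } else {
          meta$duration_seconds
        },
        duration_sd = 0,
        leadin_mean = spec$leadin_mean, leadin_sd = spec$leadin_sd
      )
      rep_trial <- simulate_trial(sub, seed,
        trial_id = target_id,
        panel_id = meta$panel_id, replicate = meta$replicate
      )
      as_tibble(rep_trial)
    },
    time_shifted = {
      seg <- trial_segments(trials)
      seg <- seg[seg$trial_id == target_id, ]
      lead <- seg[seg$attribute == "none", ]
      sel <- seg[seg$attribute != "none", ]
      if (nrow(sel) == 0L) {
        target # nothing to reverse in a selection-free trial
      } else {
        # reverse the selection portion [t0, 1] in place, keeping any
        # "none" lead where it is so every duration is preserved exactly
        t0 <- min(sel$t_left)
        new_left <- t0 + 1 - sel$t_right
        sel <- tibble(attribute = sel$attribute, t_left = new_left)
        sel <- sel[order(sel$t_left), ]
        tibble(
          trial_id = target_id, panel_id = meta$panel_id,
          replicate = meta$replicate,
          attribute = c(lead$attribute, sel$attribute),
          onset = c(lead$t_left, sel$t_left),
          duration_seconds = meta$duration_seconds
        )
      }
    }
  )
  tds_trialset(dplyr::bind_rows(others, new_rows), lexicon(trials))
}

#' Strawberry-like semi-Markov preset
#'
#' An 8-attribute preset (sweet, sour, fruity, green, watery, juicy,
#' aromatic, light) emulating the temporal signature typical of
#' strawberry panels: sweet, juicy, fruity and watery dominate the early
#' phase, aromatic peaks in the middle, and sour rises mid-task and stays
#' dominant to the end with light as a late aftertaste. Task duration
#' averages 30 s (sd 5 s), sojourns are gamma with mean 3 s and sd 1.5 s
#' (switch gaps of about a second or more), and a short `"none"` lead-in
#' (mean 1 s) precedes the first press.
#'
#' @return A [semi_markov_spec()].
#' @export
strawberry_spec <- function() {
  lex <- tds_lexicon(c(
    "sweet", "sour", "fruity", "green", "watery", "juicy", "aromatic",
    "light"
  ))
  # phase attractiveness: rows early/middle/late, columns as in lex
  W <- rbind(
    early  = c(0.30, 0.03, 0.20, 0.03, 0.15, 0.25, 0.02, 0.02),
    middle = c(0.10, 0.30, 0.10, 0.05, 0.05, 0.10, 0.25, 0.05),
    late   = c(0.08, 0.40, 0.06, 0.05, 0.05, 0.06, 0.10, 0.20)
  )
  phase_T <- lapply(seq_len(3L), function(ph) {
    T <- matrix(rep(W[ph, ], each = 8L), 8L, 8L)
    diag(T) <- 0
    T / rowSums(T)
  })
  semi_markov_spec(
    lexicon = lex,
    initial = W[1L, ] / sum(W[1L, ]),
    phase_transitions = phase_T,
    sojourn_mean = 3, sojourn_sd = 1.5, sojourn_family = "gamma",
    duration_mean = 30, duration_sd = 5,
    leadin_mean = 1, leadin_sd = 0.5
  )
}
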