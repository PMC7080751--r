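## Named parameter presets for the tissues with tabulated progenitor
## parameters (rate /week, symmetric-division probability, progenitor
## fraction, refractory minimum cycle in days). The gamma shape of the
## cycle law is not tabulated anywhere; the package fixes shape = 8 as its
## default narrow ("conservative") law — see the methods vignette.
SP_PRESETS <- list(
  "esophagus-lrig1" = list(lambda = 2.9, r = 0.10, rho = 0.65, t_min = 0.5),
  "esophagus-ahyfp" = list(lambda = 2.9, r = 0.06, rho = 0.56, t_min = 0.5),
  "paw"             = list(lambda = 2.0, r = 0.14, rho = 0.53, t_min = 1),
  "ear"             = list(lambda = 1.5, r = 0.04, rho = 0.54, t_min = 1),
  "dorsum"          = list(lambda = 1.2, r = 0.04, rho = 0.61, t_min = 2))

#' Tissue parameter presets
#'
#' Returns a ready-made [sp_params()] object for a named tissue preset
#' with its inferred progenitor parameters and a shifted-gamma cycle law
#' (shape 8, site-specific refractory minimum).
#'
#' @param name one of `r paste0('"', names(SP_PRESETS), '"', collapse = ", ")`
#' @param shape gamma shape of the cycle law (default 8)
#' @return an [sp_params()] object
#' @examples
#' sp_preset("esophagus-lrig1")
#' @export
sp_preset <- function(name, shape = 8) {
  if (!name %in% names(SP_PRESETS))
    abort_invalid(sprintf("unknown preset '%s'; available: %s", name,
                          paste(names(SP_PRESETS), collapse = ", ")))
  p <- SP_PRESETS[[name]]
  sp_params(
    lambda = p$lambda, r = p$r, rho = p$rho,
    cycle = cycle_distribution("shifted_gamma",
                               mean_cycle = rate_to_mean_cycle(p$lambda),
                               shape = shape, t_min = p$t_min))
}

#' Experimental design descriptions for the synthetic generators
#'
#' `lineage_design()` describes a lineage-tracing time course: sampling
#' times, animals and target surviving-clone counts per time point, the
#' labeling efficiency, and the initial-cell mode. `chase_design()`
#' describes an H2B-GFP dilution chase: chase times, animals per time,
#' fields of view per animal, cells per field, the leukocyte
#' contamination fraction, the between-field intensity variation, the
#' measurement noise, and the initial intensity law. Defaults reproduce
#' the reference study designs (about 300 clones per time point at
#' 10/30/84/180 days from 3/3/6/4 mice; chases at 0/7/12/18 days with at
#' least 5 fields of view per animal).
#'
#' @param times sampling times (days)
#' @param animals animals per time point
#' @param target_clones target surviving clones per time point
#' @param labeling_efficiency labeled fraction of basal cells at induction
#' @param initial initial-cell mode for each induced clone
#' @return a list of class `lineage_design` / `chase_design`
#' @export
lineage_design <- function(times = c(10, 30, 84, 180),
                           animals = c(3, 3, 6, 4),
                           target_clones = c(300, 315, 302, 305),
                           labeling_efficiency = 1 / 300,
                           initial = c("progenitor",
                                       "basal_representative")) {
  initial <- match.arg(initial)
  stopifnot(length(animals) == length(times),
            length(target_clones) == length(times),
            all(animals >= 1), all(target_clones >= 1))
  if (labeling_efficiency <= 0 || labeling_efficiency >= 1)
    abort_invalid("`labeling_efficiency` must lie in (0, 1).")
  structure(list(times = times, animals = animals,
                 target_clones = target_clones,
                 labeling_efficiency = labeling_efficiency,
                 initial = initial),
            class = "lineage_design")
}

#' @rdname lineage_design
#' @param chase_times chase times (days), including 0
#' @param fields_per_animal fields of view per animal
#' @param cells_per_field measured basal cells per field of view
#' @param leukocyte_fraction fraction of measured nuclei that are
#'   label-retaining CD45+ leukocytes
#' @param field_cv CV of the lognormal between-field intensity offset
#' @param noise_cv CV of the lognormal per-cell measurement noise
#' @param init_intensity list with `mean` and `cv` of the lognormal
#'   initial intensity law
#' @export
chase_design <- function(chase_times = c(0, 7, 12, 18),
                         animals = c(3, 3, 3, 2),
                         fields_per_animal = 5,
                         cells_per_field = 135,
                         leukocyte_fraction = 0.02,
                         field_cv = 0.1, noise_cv = 0.2,
                         init_intensity = list(mean = 1, cv = 0.35)) {
  if (!any(chase_times == 0))
    abort_invalid("`chase_times` must include 0.")
  if (length(animals) == 1) animals <- rep(animals, length(chase_times))
  if (length(animals) != length(chase_times))
    abort_invalid("`animals` must have one entry per chase time.")
  stopifnot(all(animals >= 1), fields_per_animal >= 1, cells_per_field >= 1)
  if (leukocyte_fraction < 0 || leukocyte_fraction >= 1)
    abort_invalid("`leukocyte_fraction` must lie in [0, 1).")
  if (field_cv < 0 || noise_cv < 0)
    abort_invalid("variation CVs must be non-negative.")
  structure(list(chase_times = chase_times, animals = animals,
                 fields_per_animal = fields_per_animal,
                 cells_per_field = cells_per_field,
                 leukocyte_fraction = leukocyte_fraction,
                 field_cv = field_cv, noise_cv = noise_cv,
                 init_intensity = init_intensity),
            class = "chase_design")
}

#' Generate a synthetic lineage-tracing experiment
#'
#' Emulates a clonal labeling time course under known truth: for each
#' animal, clones are induced (initial-cell mode per the design),
#' simulated to the animal's sampling time with the exact event-driven
#' engine, and recorded if they retain at least one basal cell. The
#' number of induced clones per animal is set so the expected surviving
#' count matches the design target (a pilot ensemble estimates the
#' survival probability), so emitted counts fluctuate binomially around
#' the targets.
#'
#' @param truth an [sp_params()] object (the generating truth)
#' @param design a [lineage_design()]
#' @param seed optional integer seed (same seed, byte-identical table)
#' @return a clone-table tibble (`mouse_id`, `time_days`, `clone_id`,
#'   `n_basal`, `n_suprabasal`)
#' @export
generate_lineage_experiment <- function(truth, design = lineage_design(),
                                        seed = NULL) {
  stopifnot(is_sp_params(truth), inherits(design, "lineage_design"))
  with_seed(seed, {
    rows <- purrr::map(seq_along(design$times), function(i) {
      tt <- design$times[i]
      n_anim <- design$animals[i]
      quota <- design$target_clones[i] / n_anim
      # pilot survival estimate at this time point
      p_surv <- if (tt == 0) 1 else {
        pilot <- run_engine_sizes(truth, 2000L, tt, design$initial)
        max(mean(pilot$n_progenitor + pilot$n_diff_basal >= 1), 0.01)
      }
      n_induced <- max(1L, as.integer(ceiling(quota / p_surv)))
      purrr::map_dfr(seq_len(n_anim), function(a) {
        out <- run_engine_sizes(truth, n_induced, tt, design$initial)
        basal <- as.integer(out$n_progenitor + out$n_diff_basal)
        supra <- as.integer(out$n_suprabasal)
        keep <- basal >= 1
        tibble::tibble(
          mouse_id = sprintf("d%g_m%d", tt, a),
          time_days = tt,
          clone_id = sprintf("d%g_m%d_c%d", tt, a, seq_len(sum(keep))),
          n_basal = basal[keep],
          n_suprabasal = supra[keep])
      })
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic H2B-GFP chase experiment
#'
#' Emulates the cross-sectional dilution design: each animal carries its
#' own homeostatic basal population simulated from chase start to its
#' sampling time, cells are assigned to fields of view with a lognormal
#' per-field intensity offset, multiplicative measurement noise is
#' applied, and non-diluting CD45+ leukocyte records are injected at the
#' design fraction with truthful flags.
#'
#' @param truth an [sp_params()] object
#' @param design a [chase_design()]
#' @param seed optional integer seed
#' @return an intensity-table tibble (`mouse_id`, `time_days`, `fov_id`,
#'   `cell_id`, `intensity`, `is_leukocyte`)
#' @export
generate_h2bgfp_experiment <- function(truth, design = chase_design(),
                                       seed = NULL) {
  stopifnot(is_sp_params(truth), inherits(design, "chase_design"))
  n_per_animal <- design$fields_per_animal * design$cells_per_field
  with_seed(seed, {
    rows <- purrr::map(seq_along(design$chase_times), function(i) {
      tt <- design$chase_times[i]
      purrr::map_dfr(seq_len(design$animals[i]), function(a) {
        mouse <- sprintf("d%g_m%d", tt, a)
        # oversize the starting population so the (fluctuating) basal pool
        # at the chase time still fills every field of view
        sim <- simulate_dilution(
          truth, chase_times = unique(c(0, tt)),
          n_initial_cells = ceiling(1.3 * n_per_animal),
          init_intensity = design$init_intensity,
          measurement_noise_cv = 0)
        pool <- sim$intensity[sim$time_days == tt]
        n_ker_f <- round(design$cells_per_field *
                           (1 - design$leukocyte_fraction))
        n_leu_f <- design$cells_per_field - n_ker_f
        pool <- sample(pool, min(length(pool),
                                 n_ker_f * design$fields_per_animal))
        purrr::map_dfr(seq_len(design$fields_per_animal), function(f) {
          off <- rlnorm_mean_cv(1, 1, design$field_cv)
          ker_idx <- ((f - 1) * n_ker_f + 1):min(f * n_ker_f, length(pool))
          ker <- pool[ker_idx]
          leu <- rlnorm_mean_cv(n_leu_f, design$init_intensity$mean,
                                design$init_intensity$cv)
          ints <- c(ker, leu) * off *
            rlnorm_mean_cv(length(ker) + n_leu_f, 1, design$noise_cv)
          tibble::tibble(
            mouse_id = mouse, time_days = tt,
            fov_id = sprintf("%s_f%d", mouse, f),
            cell_id = sprintf("%s_f%d_n%d", mouse, f,
                              seq_along(ints)),
            intensity = ints,
            is_leukocyte = c(rep(FALSE, length(ker)), rep(TRUE, n_leu_f)))
        })
      })
    })
    dplyr::bind_rows(rows)
  })
}
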