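## Shared fixtures, built in code.

eso_params <- function(shape = 8) sp_preset("esophagus-lrig1", shape = shape)

## Small chase design used where full-size histograms are not needed.
small_chase <- function(...) {
  chase_design(animals = c(2, 2, 2, 2), fields_per_animal = 4,
               cells_per_field = 80, ...)
}

## Direct Gillespie simulation of the Markovian single-progenitor model:
## every progenitor divides at rate lambda (exponential clock), every
## differentiating basal cell stratifies at rate Gamma. Independent of
## the event-queue engine; used as its oracle.
gillespie_sp_basal <- function(lambda_day, r, gamma_day, t_end) {
  np <- 1L; nd <- 0L; t <- 0
  repeat {
    rate <- np * lambda_day + nd * gamma_day
    if (rate == 0) return(0L)
    t <- t + rexp(1, rate)
    if (t > t_end) return(np + nd)
    if (runif(1) < np * lambda_day / rate) {
      u <- runif(1)
      if (u < r) np <- np + 1L
      else if (u < 2 * r) { np <- np - 1L; nd <- nd + 2L }
      else nd <- nd + 1L
    } else {
      nd <- nd - 1L
    }
  }
}

## Build a minimal valid intensity table.
toy_intensity_table <- function() {
  tibble::tibble(
    mouse_id = rep(c("m1", "m2"), each = 6),
    time_days = rep(c(0, 0, 0, 7, 7, 7), 2),
    fov_id = rep(c("f1", "f2"), 6),
    cell_id = sprintf("c%d", 1:12),
    intensity = c(2, 4, 6, 1, 2, 3, 2, 4, 6, 1, 2, 3),
    is_leukocyte = FALSE)
}
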