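# Synthetic per-section PV+ cell counts: (over)dispersed Poisson counts at
# a genotype-dependent mean density times a variable section area.

#' Configuration for the PV+ section-count simulator
#'
#' Default mean densities are the two cohort values the analysis layer is
#' designed around (93.3 and 114.9 cells/mm^2).
#'
#' @param n_animals named vector, animals per genotype
#'   (default `c(WT = 4, TS = 7)`).
#' @param sections_per_animal at least 8.
#' @param mean_density named per-genotype mean density, cells/mm^2.
#' @param section_area_mean,section_area_sd mm^2 (areas truncated at
#'   0.1 mm^2).
#' @param overdispersion gamma-mixing variance multiplier: 0 = pure
#'   Poisson; > 0 draws the per-section rate from a gamma with that excess
#'   coefficient of variation squared.
#' @param seed integer seed.
#' @return validated list of class `section_sim_config`.
#' @export
section_sim_config <- function(n_animals = c(WT = 4, TS = 7),
                               sections_per_animal = 12,
                               mean_density = c(WT = 93.3, TS = 114.9),
                               section_area_mean = 1.5, section_area_sd = 0.3,
                               overdispersion = 0, seed = 1L) {
  cfg <- list(n_animals = n_animals, sections_per_animal = sections_per_animal,
              mean_density = mean_density,
              section_area_mean = section_area_mean,
              section_area_sd = section_area_sd,
              overdispersion = overdispersion, seed = as.integer(seed))
  stopifnot(all(mean_density > 0), sections_per_animal >= 8,
            length(n_animals) == 2, section_area_mean > 0,
            section_area_sd >= 0, overdispersion >= 0)
  class(cfg) <- "section_sim_config"
  cfg
}

#' Simulate per-section PV+ cell counts
#'
#' Counts are Poisson (or gamma-Poisson when `overdispersion > 0`) with
#' mean `density x area`; density = count/area is computed per section.
#'
#' @param cfg a [section_sim_config()].
#' @return data.frame of class `section_table`: `animal`, `genotype`,
#'   `section`, `count`, `area_mm2`, `density`.
#' @export
generate_pv_sections <- function(cfg) {
  stopifnot(inherits(cfg, "section_sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  gt <- names(cfg$n_animals) %||% c("WT", "TS")
  rows <- list()
  for (g in seq_along(gt)) {
    for (a in seq_len(cfg$n_animals[g])) {
      aid <- sprintf("%s_%02d", gt[g], a)
      ns <- cfg$sections_per_animal
      area <- pmax(0.1, rnorm(ns, cfg$section_area_mean, cfg$section_area_sd))
      mu <- cfg$mean_density[gt[g]] * area
      lambda <- if (cfg$overdispersion > 0) {
        shape <- 1 / cfg$overdispersion
        mu * rgamma(ns, shape = shape, rate = shape)
      } else mu
      count <- rpois(ns, lambda)
      rows[[aid]] <- data.frame(animal = aid, genotype = gt[g],
                                section = seq_len(ns), count = count,
                                area_mm2 = area, density = count / area,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$genotype <- factor(out$genotype, levels = gt)
  class(out) <- c("section_table", "data.frame")
  out
}
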