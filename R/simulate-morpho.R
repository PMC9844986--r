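#' Parameters for the synthetic morphometry-table generator
#'
#' Configures [simulate_morphometry()], which emulates a transmission
#' electron microscopy (TEM) measurement campaign on cardiomyocyte surface
#' crests: nested sampling of animals, cells per animal and crests per
#' cell, with animal-level random effects so the animal is the nesting
#' unit. The default design mirrors the common two-group weanling vs.
#' young-adult comparison: 6 animals per group, 4-8 cells per animal and
#' enough crests per cell to reach roughly 70 crests per animal.
#'
#' Default group means are synthetic (chosen at biologically plausible
#' scales, not measured values); their P20 -> P60 directions follow the
#' reported maturation pattern: crest height (hence crest/sarcomere ratio),
#' SSM count per crest, SSM area and sarcomere height increase; the lateral
#' membrane interspace decreases; sarcomere length and myofibril count are
#' unchanged.
#'
#' @param groups character vector of group labels.
#' @param n_animals_per_group animals per group (>= 1).
#' @param cells_per_animal integer length-2 range; the number of cells per
#'   animal is drawn uniformly from it.
#' @param crests_per_cell crests measured per cell.
#' @param interspace_sites_per_cell lateral-interspace sites per cell; each
#'   site contributes five independent measurements, following the standard
#'   interspace protocol.
#' @param metrics named list configuring each metric; every entry has
#'   `mean` (named by group), `animal_sd` (SD of the animal-level random
#'   effect), `sd` (per-structure SD), `unit` and `level` (one of
#'   `"crest"`, `"ssm"`, `"cell"`, `"site"`). Defaults cover
#'   `crest_height_um`, `sarcomere_length_um`, `ssm_count`, `ssm_area_um2`,
#'   `sarcomere_height_um`, `lateral_interspace_nm`, `myofibril_count`.
#'   Supplied entries are merged over the defaults.
#' @param seed RNG seed (same seed, same table). `NULL` uses the current
#'   stream.
#' @return a validated `morpho_params` list.
#' @export
morpho_params <- function(groups = c("P20", "P60"),
                          n_animals_per_group = 6L,
                          cells_per_animal = c(4L, 8L),
                          crests_per_cell = 12L,
                          interspace_sites_per_cell = 2L,
                          metrics = list(), seed = NULL) {
  if (!is.character(groups) || length(groups) < 1L || anyDuplicated(groups)) {
    stop_validation("groups must be distinct labels")
  }
  check_scalar(n_animals_per_group, "n_animals_per_group",
               positive = TRUE, integerish = TRUE)
  if (!is.numeric(cells_per_animal) || length(cells_per_animal) != 2L ||
      any(cells_per_animal < 1) || cells_per_animal[1] > cells_per_animal[2]) {
    stop_validation("cells_per_animal must be an increasing range >= 1")
  }
  check_scalar(crests_per_cell, "crests_per_cell",
               positive = TRUE, integerish = TRUE)
  check_scalar(interspace_sites_per_cell, "interspace_sites_per_cell",
               positive = TRUE, integerish = TRUE)

  defaults <- default_morpho_metrics(groups)
  if (length(metrics)) {
    for (nm in names(metrics)) {
      if (is.null(defaults[[nm]])) defaults[[nm]] <- metrics[[nm]]
      else defaults[[nm]] <- modifyList(defaults[[nm]], metrics[[nm]])
    }
  }
  for (nm in names(defaults)) {
    cfg <- defaults[[nm]]
    cfg$mean <- unlist(cfg$mean)  # tolerate list-valued config (YAML/JSON)
    defaults[[nm]] <- cfg
    if (!all(groups %in% names(cfg$mean))) {
      stop_validation("metric ", nm, " lacks a mean for every group")
    }
    if (any(cfg$mean[groups] <= 0)) {
      stop_validation("metric ", nm, ": all group means must be > 0")
    }
    if (cfg$animal_sd < 0 || cfg$sd < 0) {
      stop_validation("metric ", nm, ": SDs must be >= 0")
    }
  }
  structure(
    list(
      groups = groups,
      n_animals_per_group = as.integer(n_animals_per_group),
      cells_per_animal = as.integer(round(cells_per_animal)),
      crests_per_cell = as.integer(crests_per_cell),
      interspace_sites_per_cell = as.integer(interspace_sites_per_cell),
      metrics = defaults, seed = seed
    ),
    class = "morpho_params"
  )
}

# Synthetic default scales; directions follow the reported P20 -> P60
# maturation pattern, magnitudes are configuration, not measured values.
default_morpho_metrics <- function(groups) {
  two <- function(lo, hi) {
    v <- seq(lo, hi, length.out = max(length(groups), 2L))[seq_along(groups)]
    setNames(v, groups)
  }
  list(
    crest_height_um = list(
      mean = two(0.25, 0.45), animal_sd = 0.04, sd = 0.08,
      unit = "um", level = "crest"
    ),
    sarcomere_length_um = list(
      mean = setNames(rep(1.9, length(groups)), groups),
      animal_sd = 0.05, sd = 0.15, unit = "um", level = "crest"
    ),
    ssm_count = list(
      mean = two(2, 4), animal_sd = 0.3, sd = 1.1,
      unit = "count", level = "crest"
    ),
    ssm_area_um2 = list(
      mean = two(0.25, 0.45), animal_sd = 0.03, sd = 0.10,
      unit = "um2", level = "ssm"
    ),
    sarcomere_height_um = list(
      mean = two(0.9, 1.3), animal_sd = 0.05, sd = 0.15,
      unit = "um", level = "cell"
    ),
    lateral_interspace_nm = list(
      mean = two(60, 30), animal_sd = 5, sd = 10,
      unit = "nm", level = "site"
    ),
    myofibril_count = list(
      mean = setNames(rep(25, length(groups)), groups),
      animal_sd = 1.5, sd = 3, unit = "count", level = "cell"
    )
  )
}

#' Simulate a nested morphometry table
#'
#' Draws a long-format measurement table emulating TEM crest morphometry.
#' For each metric an animal-level random effect is drawn first
#' (`N(0, animal_sd^2)`, shared by every structure in that animal), then
#' per-structure noise (`N(0, sd^2)`), so between-animal correlation is
#' built in and the animal is the correct unit of analysis. Count metrics
#' (`ssm_count`, `myofibril_count`) are rounded to integers and floored at
#' zero (one for myofibrils); continuous metrics are floored at 1% of the
#' group mean to keep all measurements positive.
#'
#' Each crest contributes one `crest_height_um` row, one
#' `sarcomere_length_um` row (the first myofibril layer below that crest,
#' sharing the crest's `structure_id`), one `ssm_count` row, and
#' `ssm_count` rows of `ssm_area_um2` (ids `<crest>_ssm<j>`). Each cell
#' contributes `sarcomere_height_um` and `myofibril_count` rows and
#' `interspace_sites_per_cell` sites of five `lateral_interspace_nm`
#' measurements (ids `<site>_m<j>`).
#'
#' @param params a [morpho_params()] object.
#' @return a data.frame with columns `group`, `animal_id`, `cell_id`,
#'   `structure_id`, `metric`, `value`, `unit`.
#' @examples
#' tab <- simulate_morphometry(morpho_params(seed = 1))
#' head(tab)
#' @export
simulate_morphometry <- function(params) {
  stopifnot(inherits(params, "morpho_params"))
  p <- params
  with_seed(p$seed, {
    rows <- list()
    add <- function(group, animal, cell, sid, metric, value, unit) {
      rows[[length(rows) + 1L]] <<- list(group, animal, cell, sid, metric,
                                         as.numeric(value), unit)
    }
    draw <- function(metric, group, animal_effect, n) {
      cfg <- p$metrics[[metric]]
      x <- cfg$mean[[group]] + animal_effect + rnorm(n, sd = cfg$sd)
      if (metric == "myofibril_count") {
        pmax(round(x), 1)
      } else if (metric == "ssm_count") {
        pmax(round(x), 0)
      } else {
        pmax(x, 0.01 * cfg$mean[[group]])
      }
    }
    for (g in p$groups) {
      for (a in seq_len(p$n_animals_per_group)) {
        animal <- sprintf("%s_a%02d", g, a)
        eff <- vapply(p$metrics, function(cfg) {
          if (cfg$animal_sd > 0) rnorm(1, sd = cfg$animal_sd) else 0
        }, numeric(1))
        n_cells <- if (p$cells_per_animal[1] == p$cells_per_animal[2]) {
          p$cells_per_animal[1]
        } else {
          sample(p$cells_per_animal[1]:p$cells_per_animal[2], 1L)
        }
        for (cc in seq_len(n_cells)) {
          cell <- sprintf("%s_c%02d", animal, cc)
          for (cr in seq_len(p$crests_per_cell)) {
            sid <- sprintf("%s_crest%02d", cell, cr)
            ch <- draw("crest_height_um", g, eff[["crest_height_um"]], 1L)
            sl <- draw("sarcomere_length_um", g,
                       eff[["sarcomere_length_um"]], 1L)
            sc <- draw("ssm_count", g, eff[["ssm_count"]], 1L)
            add(g, animal, cell, sid, "crest_height_um", ch, "um")
            add(g, animal, cell, sid, "sarcomere_length_um", sl, "um")
            add(g, animal, cell, sid, "ssm_count", sc, "count")
            if (sc > 0) {
              areas <- draw("ssm_area_um2", g, eff[["ssm_area_um2"]], sc)
              for (j in seq_len(sc)) {
                add(g, animal, cell, sprintf("%s_ssm%02d", sid, j),
                    "ssm_area_um2", areas[j], "um2")
              }
            }
          }
          add(g, animal, cell, sprintf("%s_sarc", cell),
              "sarcomere_height_um",
              draw("sarcomere_height_um", g,
                   eff[["sarcomere_height_um"]], 1L), "um")
          add(g, animal, cell, sprintf("%s_myof", cell),
              "myofibril_count",
              draw("myofibril_count", g, eff[["myofibril_count"]], 1L),
              "count")
          for (s in seq_len(p$interspace_sites_per_cell)) {
            site <- sprintf("%s_site%02d", cell, s)
            vals <- draw("lateral_interspace_nm", g,
                         eff[["lateral_interspace_nm"]], 5L)
            for (j in 1:5) {
              add(g, animal, cell, sprintf("%s_m%d", site, j),
                  "lateral_interspace_nm", vals[j], "nm")
            }
          }
        }
      }
    }
    data.frame(
      group = vapply(rows, `[[`, "", 1L),
      animal_id = vapply(rows, `[[`, "", 2L),
      cell_id = vapply(rows, `[[`, "", 3L),
      structure_id = vapply(rows, `[[`, "", 4L),
      metric = vapply(rows, `[[`, "", 5L),
      value = vapply(rows, `[[`, 0, 6L),
      unit = vapply(rows, `[[`, "", 7L),
      stringsAsFactors = FALSE
    )
  })
}
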