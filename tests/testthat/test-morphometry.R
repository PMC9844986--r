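test_that("normalized crest height is the plain ratio and is scale invariant", {
  expect_equal(normalized_crest_height(0.5, 2.0), 0.25)
  expect_equal(normalized_crest_height(1.8, 1.8), 1.0)
  # multiplying both lengths by any c leaves the ratio unchanged (exact)
  set.seed(2)
  ch <- runif(20, 0.1, 1); sl <- runif(20, 1.5, 2.3); cc <- runif(20, 0.5, 3)
  expect_equal(normalized_crest_height(cc * ch, cc * sl),
               normalized_crest_height(ch, sl), tolerance = 1e-12)
  expect_error(normalized_crest_height(0.5, 0),
               class = "crestscope_validation")
  expect_error(normalized_crest_height(0.5, -2),
               class = "crestscope_validation")
})

test_that("crest_ratios pairs heights with their sarcomere lengths", {
  tab <- simulate_morphometry(morpho_params(
    n_animals_per_group = 2L, cells_per_animal = c(2L, 2L),
    crests_per_cell = 3L, seed = 4
  ))
  cr <- crest_ratios(tab)
  expect_true(all(cr$metric == "crest_ratio"))
  expect_equal(nrow(cr), sum(tab$metric == "crest_height_um"))
  sid <- cr$structure_id[1]
  expect_equal(
    cr$value[1],
    tab$value[tab$structure_id == sid & tab$metric == "crest_height_um"] /
      tab$value[tab$structure_id == sid &
                  tab$metric == "sarcomere_length_um"]
  )
})

test_that("summarize_morphometry aggregates correctly at each nesting level", {
  # hand-built table: two animals with per-animal means 1 and 3
  tab <- data.frame(
    group = "G", animal_id = rep(c("a1", "a2"), c(4L, 2L)),
    cell_id = "c1",
    structure_id = paste0("s", 1:6), metric = "crest_height_um",
    value = c(0.5, 1.5, 0.5, 1.5, 3, 3), unit = "um",
    stringsAsFactors = FALSE
  )
  s_an <- summarize_morphometry(tab, "crest_height_um", "animal")
  expect_equal(s_an$mean, 2)           # mean of per-animal means (1, 3)
  expect_equal(s_an$n_units, 2L)
  s_st <- summarize_morphometry(tab, "crest_height_um", "structure")
  expect_equal(s_st$mean, mean(tab$value))
  expect_equal(s_st$n_units, 6L)
  # constant metric: sd 0
  tab$value <- 5
  s_c <- summarize_morphometry(tab, "crest_height_um", "structure")
  expect_equal(s_c$mean, 5)
  expect_equal(s_c$sd, 0)
  expect_error(summarize_morphometry(tab, "nope"),
               class = "crestscope_validation")
})

test_that("one structure per animal makes structure and animal nesting agree", {
  tab <- data.frame(
    group = rep(c("A", "B"), each = 3),
    animal_id = paste0("a", 1:6), cell_id = "c1",
    structure_id = paste0("s", 1:6), metric = "myofibril_count",
    value = c(20, 24, 22, 25, 27, 26), unit = "count",
    stringsAsFactors = FALSE
  )
  s1 <- summarize_morphometry(tab, "myofibril_count", "structure")
  s2 <- summarize_morphometry(tab, "myofibril_count", "animal")
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  expect_equal(s1$n_units, s2$n_units)
})

test_that("validate_morphometry flags schema and measurement violations", {
  tab <- simulate_morphometry(morpho_params(
    n_animals_per_group = 2L, cells_per_animal = c(2L, 2L),
    crests_per_cell = 2L, seed = 6
  ))
  expect_equal(nrow(validate_morphometry(tab)), 0L)

  bad <- tab
  # drop one ssm area row -> count/area mismatch for its crest
  area_rows <- which(bad$metric == "ssm_area_um2")
  if (length(area_rows)) {
    victim <- bad$structure_id[area_rows[1]]
    bad <- bad[-area_rows[1], ]
    rep1 <- validate_morphometry(bad)
    expect_true(any(rep1$rule == "ssm_mismatch"))
    expect_true(any(grepl(sub("_ssm[0-9]+$", "", victim),
                          rep1$structure_id)))
  }
  bad2 <- tab
  bad2$value[bad2$metric == "lateral_interspace_nm"][1] <- -5
  expect_true(any(validate_morphometry(bad2)$rule ==
                    "nonpositive_interspace"))
  bad3 <- tab
  bad3$value[bad3$metric == "crest_height_um"][1] <- 0
  expect_true(any(validate_morphometry(bad3)$rule == "nonpositive_length"))
  bad4 <- tab[, setdiff(names(tab), "unit")]
  expect_true(any(validate_morphometry(bad4)$rule == "schema"))
})

test_that("CSV write/read round-trips the table", {
  tab <- simulate_morphometry(morpho_params(
    n_animals_per_group = 2L, cells_per_animal = c(2L, 3L),
    crests_per_cell = 2L, seed = 8
  ))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_morphometry(tab, path)
  back <- read_morphometry(path)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$structure_id, tab$structure_id)
  expect_identical(back$group, tab$group)
  expect_identical(back$metric, tab$metric)
})
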