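make_panel_config <- function(seed = 1, n_species = 3,
                              uncertainty = FALSE) {
  panel <- generate_species_panel(n_species = n_species)
  des <- recovery_design()
  species <- lapply(panel, function(sp) {
    list(label = sp$label,
         dataset = generate_test(sp$sd, des, seed = seed,
                                 species = sp$label))
  })
  profiles <- list(
    list(label = "pulse", scenario = "single-sharp-peak", peak_conc = 10),
    list(label = "long-tail", scenario = "single-peak-slow-decline",
         peak_conc = 10),
    list(label = "multi", scenario = "multi-peak", peak_conc = 10))
  list(seed = seed, variants = c("SD", "IT"), x = 50,
       uncertainty = uncertainty, species = species, profiles = profiles)
}

test_that("the study driver produces a complete LP50 table, SSDs and rankings", {
  cfg <- make_panel_config(seed = 2, n_species = 3)
  study <- suppressMessages(run_study(cfg))
  expect_equal(nrow(study$lp50), 3 * 3 * 2)  # species x profiles x variants
  expect_true(all(study$lp50$lp50 > 0))
  expect_equal(nrow(study$hp5), 3 * 2)
  expect_true(all(study$hp5$hp5 > 0))
  expect_length(study$fits, 6L)
  # LP50 cells equal a direct prediction with the same fitted parameters
  for (i in c(1L, 8L, nrow(study$lp50))) {
    row <- study$lp50[i, ]
    f <- study$fits[[paste(row$species, row$variant, sep = ".")]]
    expect_equal(row$lp50,
                 lpx(f$params, study$profiles[[row$profile]], x = 50))
  }
  # slow vs fast panel members reverse ranking between pulse and long tail,
  # so the change report is non-empty by construction
  expect_gt(nrow(study$ranking$changes), 0)
})

test_that("identical species entries give identical LP50 rows; reruns reproduce", {
  cfg <- make_panel_config(seed = 5, n_species = 3)
  cfg$variants <- "SD"
  cfg$species <- cfg$species[c(1, 1, 2, 3)]
  cfg$species[[2L]]$label <- "slow-kd-copy"
  cfg$species[[2L]]$dataset$species <- "slow-kd-copy"
  study <- suppressMessages(run_study(cfg))
  a <- study$lp50[study$lp50$species == "slow-kd", ]
  b <- study$lp50[study$lp50$species == "slow-kd-copy", ]
  expect_equal(a$lp50, b$lp50)
  study2 <- suppressMessages(run_study(cfg))
  expect_identical(study$lp50$lp50, study2$lp50$lp50)
})

test_that("a YAML config with files on disk drives the full study", {
  dir <- withr::local_tempdir()
  panel <- generate_species_panel(n_species = 3)
  for (sp in panel) {
    dat <- generate_test(sp$sd, recovery_design(), seed = 4,
                         species = sp$label)
    write_survival_table(dat, file.path(dir, paste0(sp$label, ".csv")))
  }
  prof <- generate_scenario("single-sharp-peak", peak_conc = 10)
  write_exposure_profile(prof, file.path(dir, "pulse.csv"))
  cfg <- list(
    seed = 4, variants = list("SD"), x = 50,
    output_dir = file.path(dir, "out"),
    species = lapply(panel, function(sp)
      list(label = sp$label, table = paste0(sp$label, ".csv"))),
    profiles = list(list(label = "pulse", path = "pulse.csv"),
                    list(label = "tail",
                         scenario = "single-peak-slow-decline",
                         peak_conc = 10)))
  cfg_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfg_path)
  study <- suppressMessages(run_study(cfg_path))
  expect_equal(nrow(study$lp50), 3 * 2)
  for (f in c("lp50_table.csv", "hp5_table.csv", "ranking.csv",
              "ranking_changes.csv", "fit_reports.json"))
    expect_true(file.exists(file.path(dir, "out", f)))
  back <- utils::read.csv(file.path(dir, "out", "lp50_table.csv"))
  expect_equal(back$lp50, study$lp50$lp50, tolerance = 1e-12)
})

test_that("a missing survival table fails fast, naming the path", {
  cfg <- make_panel_config(n_species = 3)
  cfg$species[[2L]] <- list(label = "ghost", table = "no/such/table.csv")
  expect_error(suppressMessages(run_study(cfg)), "no/such/table.csv")
})

test_that("a species that cannot be calibrated is flagged and skipped", {
  cfg <- make_panel_config(seed = 3, n_species = 3)
  cfg$variants <- "SD"
  # a one-treatment 'dataset' cannot be calibrated at all
  broken <- survival_dataset(0:4, list(
    list(exposure = 0, survivors = rep(20L, 5))), species = "broken")
  cfg$species <- c(cfg$species, list(list(label = "broken",
                                          dataset = broken)))
  expect_warning(study <- suppressMessages(run_study(cfg)),
                 "calibration failed")
  expect_true(any(grepl("broken", study$failed)))
  expect_false("broken" %in% study$lp50$species)
  expect_equal(nrow(study$hp5), 3L)  # SSDs still built from the 3 others
})
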