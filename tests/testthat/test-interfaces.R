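# Configuration, tabular I/O and the CLI.

test_that("minimal configs are defaulted and unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("scenario:\n  n_zones: 4", path)
  cfg <- load_config(path)
  expect_equal(cfg$scenario$n_zones, 4)
  expect_equal(cfg$detector$q, 0.95)
  expect_equal(cfg$scenario$budgets, c(20, 10, 5) * 4)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("params:\n  gama: 0.5", bad)
  expect_error(load_config(bad), "gama")
  expect_error(load_config("no/such/file.yaml"), "not found")
})

test_that("config round-trip through YAML and JSON is idempotent", {
  cfg <- validate_config(list(scenario = list(n_zones = 6L,
                                              grid_shape = c(2L, 3L))))
  for (ext in c(".yaml", ".json")) {
    p1 <- withr::local_tempfile(fileext = ext)
    save_config(cfg, p1)
    cfg2 <- load_config(p1)
    p2 <- withr::local_tempfile(fileext = ext)
    save_config(cfg2, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(config_hash(cfg2), config_hash(load_config(p2)))
  }
})

test_that("zone tables round-trip losslessly and enforce unique keys", {
  set.seed(30)
  tab <- data.frame(zone_id = 0:99, row = 0L, col = 0:99,
                    u_water = runif(100) * 1e3,
                    u_fertilizer = rnorm(100),
                    u_pesticide = exp(rnorm(100, sd = 5)),
                    yield = rnorm(100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_zone_table(tab, path)
  back <- read_zone_table(path, required = names(tab))
  expect_equal(back, tab)

  dup <- tab[c(1, 2, 2), ]
  expect_error(write_zone_table(dup, path), "duplicate zone_id: 1")
  writeLines("zone_id,u_water\n3,1\n3,2", path)
  expect_error(read_zone_table(path), "duplicate zone_id: 3")
  writeLines("row,col\n0,1", path)
  expect_error(read_zone_table(path), "zone_id")

  # header-only table is valid on read
  writeLines("zone_id,u_water", path)
  expect_equal(nrow(read_zone_table(path)), 0)
})

test_that("observation bundles round-trip through the text format", {
  sc <- tiny_scenario(4)
  env <- sample_environment(sc, 0)
  obs <- render_observations(sc, env, seed = 2)
  dir <- withr::local_tempdir()
  write_observation_bundle(obs, dir)
  back <- read_observation_bundle(dir)
  expect_equal(back$x_sat, obs$x_sat, tolerance = 1e-14)
  expect_equal(back$x_weather, obs$x_weather, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("the CLI pipeline runs end to end and is deterministic", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "c.yaml")
  save_config(validate_config(list(scenario = list(n_zones = 4L,
                                                   grid_shape = c(2L, 2L)))),
              cfgp)

  out1 <- file.path(dir, "run1")
  expect_equal(cli_main(c("simulate", "--config", cfgp, "--out", out1,
                          "--seed", "7")), 0L)
  expect_true(file.exists(file.path(out1, "zones.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  out2 <- file.path(dir, "run2")
  cli_main(c("simulate", "--config", cfgp, "--out", out2, "--seed", "7"))
  expect_identical(readLines(file.path(out1, "zones.csv")),
                   readLines(file.path(out2, "zones.csv")))
  expect_identical(readLines(file.path(out1, "manifest.json")),
                   readLines(file.path(out2, "manifest.json")))

  optd <- file.path(dir, "opt")
  expect_equal(cli_main(c("optimize", "--config", cfgp, "--out", optd)), 0L)
  plan <- read_zone_table(file.path(optd, "plan.csv"),
                          required = c("zone_id", "u_water"))
  expect_equal(nrow(plan), 4)
  expect_true(all(plan$u_water >= 0))

  fused <- file.path(dir, "fused")
  expect_equal(cli_main(c("fuse", "--config", cfgp, "--bundle",
                          file.path(out1, "observation"),
                          "--out", fused)), 0L)
  expect_true(file.exists(file.path(fused, "fused.csv")))

  det <- file.path(dir, "det")
  expect_equal(cli_main(c("detect", "--config", cfgp, "--features",
                          file.path(out1, "zones.csv"), "--out", det)), 0L)
  scores <- read_zone_table(file.path(det, "scores.csv"),
                            required = c("zone_id", "score", "label"))
  expect_equal(nrow(scores), 4)

  alloc <- file.path(dir, "alloc")
  expect_equal(cli_main(c("allocate", "--config", cfgp, "--scores",
                          file.path(det, "scores.csv"),
                          "--out", alloc)), 0L)
  atab <- read_zone_table(file.path(alloc, "allocation.csv"),
                          required = c("zone_id", "u_water"))
  expect_equal(sum(atab$u_water), unname(min(4 * 20, sum(rep(30, 4)))),
               tolerance = 1e-6)

  ctrl <- file.path(dir, "ctrl")
  expect_equal(cli_main(c("control", "--config", cfgp, "--out", ctrl,
                          "--steps", "3", "--seed", "1")), 0L)
  expect_true(file.exists(file.path(ctrl, "trajectory.csv")))
})

test_that("CLI argument errors exit with usage status", {
  expect_equal(cli_main(character(0)), 2L)
  expect_equal(suppressMessages(cli_main("transmogrify")), 2L)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--out", tempfile()))), 2L)   # missing --config
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config"))), 2L)            # dangling value
})
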