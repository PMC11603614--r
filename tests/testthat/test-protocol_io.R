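test_that("COLVAR round trips byte-stably and rejects malformed input", {
  df <- data.frame(time = c(0, 0.01, 0.02), z = c(0.1, -0.23456789012345,
                                                  1e-8),
                   bias = c(0, 3.5, 7.123456))
  traj <- colvar_trajectory(df)
  p1 <- tempfile(); p2 <- tempfile()
  write_colvar(traj, p1)
  expect_true(startsWith(readLines(p1, n = 1), "#! FIELDS time z bias"))
  back <- read_colvar(p1)
  expect_equal(as.data.frame(back), df, tolerance = 1e-15,
               ignore_attr = TRUE)
  write_colvar(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # header-only file: empty trajectory, no error
  p3 <- tempfile()
  writeLines("#! FIELDS time z", p3)
  empty <- read_colvar(p3)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("time", "z"))
  # contract violations
  p4 <- tempfile(); writeLines(c("0 1", "1 2"), p4)
  expect_error(read_colvar(p4), "missing '#! FIELDS'")
  p5 <- tempfile(); writeLines(c("#! FIELDS time z", "0 1", "1 2 3"), p5)
  expect_error(read_colvar(p5), "line 3")
  expect_error(colvar_trajectory(data.frame(time = c(1, 1, 2))), "increasing")
})

test_that("large-table round trip preserves random cells", {
  # scaled to 2e5 rows (a 1e6-row fixture would dominate the suite's budget;
  # the format path is identical)
  set.seed(111)
  n <- 200000L
  df <- data.frame(time = seq_len(n) * 0.002, z = rnorm(n),
                   bias = runif(n) * 50)
  p <- tempfile()
  write_colvar(colvar_trajectory(df), p)
  back <- read_colvar(p)
  expect_identical(nrow(back), n)
  idx <- sample(n, 100)
  expect_equal(back$z[idx], df$z[idx], tolerance = 1e-15)
  expect_equal(back$bias[idx], df$bias[idx], tolerance = 1e-15)
  unlink(p)
})

test_that("run_oneopes COLVAR fixtures carry the ladder's CV labels", {
  setup <- toy_binding_setup(steps = 2000L, seed = 9)
  trs <- do.call(run_oneopes, setup$run_args)
  p <- tempfile()
  write_colvar(trs[[8]], p)
  back <- read_colvar(p)
  expect_true(all(c("z", "q") %in% names(back)))
  expect_true(all(paste0("aux", 1:7, ".bias") %in% names(back)))
  expect_true(all(c("mt.bias", "opes.bias", "bias", "ene") %in% names(back)))
})

test_that("sigma from unbiased runs: plain, circular, and refusals", {
  set.seed(112)
  n <- 1000
  df <- data.frame(time = seq_len(n), cv = rnorm(n, sd = 0.3),
                   phi = atan2(sin(rnorm(n, pi, 0.3)), cos(rnorm(n, pi, 0.3))))
  traj <- colvar_trajectory(df)
  s <- compute_sigma_from_unbiased(traj, "cv")
  expect_lt(abs(s[["cv"]] - 0.3) / 0.3, 0.05)
  # wrapped series near the +/- pi seam: circular estimate stays ~0.3 where
  # the naive standard deviation explodes
  expect_gt(sd(df$phi), 1)
  sc <- compute_sigma_from_unbiased(traj, "phi",
                                    period = c(phi = 2 * pi))
  expect_lt(abs(sc[["phi"]] - 0.3) / 0.3, 0.1)
  expect_error(compute_sigma_from_unbiased(
    colvar_trajectory(data.frame(time = 1:10, cv = rep(1, 10))), "cv"),
    "constant")
  biased <- colvar_trajectory(data.frame(time = 1:10, cv = rnorm(10),
                                         bias = rep(2, 10)))
  expect_error(compute_sigma_from_unbiased(biased, "cv"), "unbiased")
})

test_that("protocol config validates, serializes and round-trips", {
  cfg <- example_protocol_config()
  expect_identical(cfg$barrier_main, 100)
  expect_identical(cfg$barrier_multicv, 3)
  expect_identical(cfg$pace_main, 10000L)
  expect_identical(cfg$pace_multicv, 20000L)
  expect_identical(cfg$pace_multithermal, 100L)
  p <- tempfile(fileext = ".yaml")
  write_protocol_config(cfg, p)
  cfg2 <- read_protocol_config(p)
  expect_equal(cfg, cfg2)
  # label uniqueness and roster coverage
  lad <- build_default_ladder()
  expect_error(protocol_config(lad, cfg$cv_specs[1:2], cfg$funnel),
               "missing definitions")
  dup <- c(cfg$cv_specs, cfg$cv_specs[1])
  expect_error(protocol_config(lad, dup, cfg$funnel), "unique")
})

test_that("emission: structure, golden bytes, idempotence, refusals", {
  cfg <- example_protocol_config()
  out <- file.path(tempdir(), "emit1")
  unlink(out, recursive = TRUE)
  paths <- emit_plumed_protocol(cfg, out)
  expect_length(paths, 8)
  expect_identical(basename(dirname(paths)), paste0("replica-", 0:7))
  # replica 0 has exactly one bias block; replica 7 has 1 + 7 + 1
  n_bias <- function(p) sum(grepl("OPES_METAD_EXPLORE|OPES_EXPANDED",
                                  readLines(p)))
  expect_identical(n_bias(paths[1]), 1L)
  expect_identical(n_bias(paths[8]), 9L)
  # every ARG label is defined before use
  for (p in paths) expect_true(check_plumed_file(p))
  # byte-identical to the committed golden tree
  golden <- system.file("extdata", "golden", package = "oneopes")
  for (k in 0:7) {
    g <- file.path(golden, sprintf("replica-%d", k), "plumed.dat")
    e <- file.path(out, sprintf("replica-%d", k), "plumed.dat")
    expect_identical(readBin(e, "raw", file.size(e)),
                     readBin(g, "raw", file.size(g)),
                     label = sprintf("replica-%d emission", k))
  }
  # idempotence: emitting again gives identical bytes
  out2 <- file.path(tempdir(), "emit2")
  unlink(out2, recursive = TRUE)
  paths2 <- emit_plumed_protocol(cfg, out2)
  expect_identical(readLines(paths[4]), readLines(paths2[4]))
  # refusals: missing sigma, missing funnel
  cfg_nosig <- cfg; cfg_nosig$sigma <- NULL
  expect_error(emit_plumed_protocol(cfg_nosig, tempfile()), "SIGMA")
  cfg_nofun <- cfg; cfg_nofun$funnel <- NULL
  expect_error(emit_plumed_protocol(cfg_nofun, tempfile()), "funnel")
  # static dependency checker flags an undefined label
  badf <- tempfile()
  writeLines(c("a: TORSION ATOMS=1,2,3,4",
               "b: OPES_METAD_EXPLORE ARG=a,zz PACE=10 BARRIER=5"), badf)
  expect_error(check_plumed_file(badf), "zz")
})

test_that("cli: metrics, analyze, emit-protocol, degenerate simulate-toy", {
  tdir <- file.path(tempdir(), "cliwork")
  dir.create(tdir, showWarnings = FALSE)
  # metrics on a 5-row CSV -> JSON with all metrics
  csv <- file.path(tdir, "aff.csv")
  writeLines(c("id,predicted,uncertainty,experimental",
               "s1,-10.2,0.3,-9.8", "s2,-8.1,0.4,-8.9", "s3,-6.6,0.2,-6.0",
               "s4,-4.9,0.5,-5.2", "s5,-3.3,0.3,-4.1"), csv)
  js <- file.path(tdir, "metrics.json")
  out <- capture.output(oneopes_cli(c("metrics", "--csv", csv, "--out", js,
                                      "--n-iter", "200", "--seed", "4")))
  expect_true(any(grepl("^# oneopes", out)))
  got <- jsonlite::fromJSON(js)
  expect_length(got$point, 7)
  # simulate-toy --steps 0: valid empty outputs
  simdir <- file.path(tdir, "sim0")
  capture.output(oneopes_cli(c("simulate-toy", "--system", "double-well",
                               "--steps", "0", "--seed", "1",
                               "--out", simdir)))
  expect_true(file.exists(file.path(simdir, "COLVAR.0")))
  expect_identical(nrow(read_colvar(file.path(simdir, "COLVAR.0"))), 0L)
  # analyze a small simulated binding fixture end to end
  simdir2 <- file.path(tdir, "simb")
  capture.output(oneopes_cli(c("simulate-toy", "--system", "binding",
                               "--steps", "20000", "--seed", "2",
                               "--out", simdir2)))
  adir <- file.path(tdir, "analysis")
  capture.output(oneopes_cli(c("analyze", "--colvar",
                               file.path(simdir2, "COLVAR.0"),
                               "--out", adir)))
  dG <- read.table(file.path(adir, "deltaG.tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(dG), 5L)  # mean, 3 blocks, std
  expect_true(all(is.finite(dG$kcal_mol)))
  # emit-protocol from a YAML config
  yml <- file.path(tdir, "cfg.yaml")
  write_protocol_config(example_protocol_config(), yml)
  pdir <- file.path(tdir, "plumed")
  capture.output(oneopes_cli(c("emit-protocol", "--config", yml,
                               "--out", pdir)))
  expect_length(list.files(pdir, pattern = "plumed.dat", recursive = TRUE), 8)
  # usage errors name the offending key
  expect_error(oneopes_cli(c("metrics", "--nope", "1")), "--nope")
  expect_error(oneopes_cli("frobnicate"), "unknown subcommand")
  expect_error(oneopes_cli(c("simulate-toy", "--system", "weird", "--out",
                             tdir)), "weird")
})
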