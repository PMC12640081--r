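test_that("species_network validates its invariants", {
  expect_s3_class(quartet_network(0.01, "inflow", "msci"), "species_network")
  # ages must decrease root -> tips
  expect_error(species_network(c(3L, 3L, NA), c(0, 0.5, 0.2), c("A", "B", "R"),
                               rep(0.01, 3)), "strictly decrease")
  # introgression time must lie inside both branch intervals
  expect_error(
    species_network(c(5L, 5L, 6L, 6L, 7L, 7L, NA),
                    c(0, 0, 0, 0, 0.01, 0.02, 0.03),
                    c("A", "B", "C", "D", "T", "S", "R"), rep(0.01, 7),
                    introgression = list(donor = "C", recipient = "A",
                                         tau = 0.015, phi = 0.2)),
    "within both")
  # a network carries one mode of gene flow, not both
  expect_error(
    species_network(c(3L, 3L, NA), c(0, 0, 0.01), c("A", "B", "R"),
                    rep(0.01, 3),
                    introgression = list(donor = "A", recipient = "B",
                                         tau = 0.005, phi = 0.1),
                    migration = data.frame(donor = "A", recipient = "B",
                                           M = 0.1)),
    "either an introgression edge or migration")
})

test_that("expected cumulative introgression probability follows the band formula", {
  # no migration, no introgression
  expect_equal(expected_cumulative_introgression(0, 0.5, 0.01), 0)
  # the published two-population worked example (printed to 3 d.p. as 0.798;
  # the rounded inputs reproduce it to within one unit in the last digit)
  phi0 <- expected_cumulative_introgression(0.568, 0.0748 - 0.0260, 0.0692)
  expect_lt(abs(phi0 - 0.798), 1.5e-3)
  # monotone in M, approaching 1
  Ms <- c(0.1, 0.5, 1, 2)
  vals <- expected_cumulative_introgression(Ms, 0.01, 0.01)
  expect_true(all(diff(vals) > 0))
  expect_gt(expected_cumulative_introgression(100, 0.01, 0.01), 1 - 1e-10)
  expect_error(expected_cumulative_introgression(0.1, 0.01, 0), "positive")
})

test_that("network yaml config round-trips", {
  net <- quartet_network(0.0025, "outflow", "msci", phi = 0.2)
  f <- tempfile(fileext = ".yaml")
  write_network_config(net, f)
  back <- read_network_config(f)
  expect_equal(back$age, net$age)
  expect_equal(back$theta, net$theta)
  expect_equal(back$introgression$phi, 0.2)
  expect_equal(back$labels[back$introgression$donor], "B")

  netm <- quartet_network(0.01, "inflow", "mscm", M = 0.1)
  f2 <- tempfile(fileext = ".yaml")
  write_network_config(netm, f2)
  backm <- read_network_config(f2)
  expect_equal(backm$migration$M, 0.1)
})
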