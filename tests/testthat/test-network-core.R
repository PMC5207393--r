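test_that("the shipped model definition has the expected structure", {
  net <- shipped()
  cnt <- network_counts(net)
  expect_identical(unname(cnt["species"]), 109L)
  expect_identical(unname(cnt["reactions"]), 138L)
  expect_identical(unname(cnt["parameters"]), 195L)
  S <- stoichiometry_matrix(net)
  expect_identical(dim(S), c(109L, 138L))
  expect_false(anyDuplicated(net$species$name) > 0)
})

test_that("degenerate and toy networks build correctly", {
  empty <- build_network(data.frame(), list())
  expect_identical(unname(network_counts(empty)), c(0L, 0L, 0L))
  expect_identical(dim(stoichiometry_matrix(empty)), c(0L, 0L))

  toy <- build_network(
    data.frame(name = c("A", "B"), compartment = "cytoplasm", init = c(1, 0)),
    list(reaction("r1", reactants = c(A = 1), products = c(B = 1), kf = "k")),
    c(k = 1))
  expect_equal(unname(stoichiometry_matrix(toy)[, "r1"]), c(-1, 1))
})

test_that("structural errors name the offender", {
  sp <- data.frame(name = "A", compartment = "cytoplasm", init = 1)
  expect_error(
    build_network(sp, list(reaction("vX", reactants = c(Qq = 1), kf = "k")),
                  c(k = 1)),
    "vX.*Qq")
  expect_error(
    build_network(sp, list(reaction("vY", reactants = c(A = 1), kf = "nope"))),
    "vY.*nope")
  expect_error(
    build_network(rbind(sp, sp), list()),
    "duplicate species")
  expect_error(
    build_network(sp, list(), c(k = 1, k = 2)),
    "duplicate parameter")
})

test_that("evaluate_rate reproduces the closed-form rate laws", {
  net <- toy_binding_network(kf = 2, kr = 0)
  # mass action: kf [A][B] = 2 * 0.5 * 0.1
  expect_equal(evaluate_rate(net$reactions$b1, c(A = 0.5, B = 0.1, C = 0),
                             net$params), 0.1)
  # Michaelis-Menten at S = Km gives Vmax/2 (enzyme at 1)
  mm <- build_network(
    data.frame(name = c("S", "P", "E"), compartment = "cytoplasm",
               init = c(1, 0, 1)),
    list(reaction("m1", kind = "michaelis_menten", reactants = c(S = 1),
                  products = c(P = 1), modifiers = "E", kf = "vmax",
                  factors = list(f_pow("E"), f_sat("S", "Km")))),
    c(vmax = 3, Km = 0.4))
  expect_equal(evaluate_rate(mm$reactions$m1, c(S = 0.4, P = 0, E = 1),
                             mm$params), 1.5)
  # Hill activation at S = K gives Vmax/2 for any exponent
  hl <- build_network(
    data.frame(name = c("TF", "G"), compartment = "nucleus", init = c(1, 0)),
    list(reaction("h1", kind = "hill_activation", products = c(G = 1),
                  modifiers = "TF", kf = "vmax",
                  factors = list(f_hill_act("TF", "K", "n")))),
    c(vmax = 8, K = 0.3, n = 2))
  expect_equal(evaluate_rate(hl$reactions$h1, c(TF = 0.3, G = 0), hl$params), 4)
  expect_error(evaluate_rate(hl$reactions$h1, c(TF = -1, G = 0), hl$params),
               "negative")
})

test_that("activation and repression Hill factors are complementary", {
  # hill_act + hill_rep at the same (S, K, n) always sum to 1, so the two
  # corresponding Vmax-scaled rates sum to Vmax
  set.seed(7)
  for (i in 1:20) {
    S <- runif(1, 0, 2); K <- runif(1, 0.1, 2); n <- sample(1:4, 1)
    a <- tsp1net:::.eval_factor_r(f_hill_act("x", K, n), c(x = S), numeric())
    r <- tsp1net:::.eval_factor_r(f_hill_rep("x", K, n), c(x = S), numeric())
    expect_equal(a + r, 1, tolerance = 1e-12)
  }
})

test_that("assembled derivatives match the per-reaction brute-force oracle", {
  net <- shipped()
  f <- assemble_derivatives(net)
  ss <- normoxic_ss()
  set.seed(1)
  for (i in 1:100) {
    state <- ss * exp(runif(length(ss), -1, 1))
    got <- f(0, state)
    want <- brute_force_rhs(net, state)
    scale <- pmax(abs(want), max(abs(want)) * 1e-9)
    expect_lt(max(abs(got - want) / scale), 1e-12)
  }
})

test_that("zero rate constants give a zero derivative field", {
  net <- shipped()
  f <- assemble_derivatives(net, params = 0 * net$params)
  expect_true(all(f(0, normoxic_ss()) == 0))
})

test_that("a closed binding system conserves total mass along trajectories", {
  net <- toy_binding_network()
  tr <- simulate_protocol(net, simulation_protocol(duration = 500,
                                                   times = seq(0, 500, 5)),
                          from_state = initial_state(net))
  totA <- tr$conc[, "A"] + tr$conc[, "C"]
  totB <- tr$conc[, "B"] + tr$conc[, "C"]
  expect_lt(max(abs(totA - totA[1])), 1e-9)
  expect_lt(max(abs(totB - totB[1])), 1e-9)
})

test_that("the model definition round-trips losslessly through YAML", {
  net <- shipped()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_network_definition(net, tmp)
  net2 <- load_network_definition(tmp)
  expect_identical(network_counts(net), network_counts(net2))
  expect_identical(net$params, net2$params)
  expect_identical(net$species$init, net2$species$init)
  st <- normoxic_ss() * 1.1
  f1 <- assemble_derivatives(net)(0, st)
  f2 <- assemble_derivatives(net2)(0, st)
  expect_identical(f1, f2)
})
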