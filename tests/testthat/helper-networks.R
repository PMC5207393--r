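## Shared fixtures: toy networks built in code, an independent brute-force
## RHS oracle, and memoised trajectories of the shipped model so that
## expensive simulations are run once per test session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- .cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .cache[[key]] <- val
  val
}

shipped <- function() memo("net", tsp1_network())

normoxic_ss <- function() memo("ss", find_steady_state(shipped(), 21, 0))

hypoxia_traj <- function() {
  memo("hyp48", simulate_oxygen_shift(shipped(), 2, 2880))
}

tgfb_traj <- function(chx = FALSE) {
  memo(paste0("tgfb1_", chx), simulate_tgfb(shipped(), 1, 2880, chx = chx))
}

## Independent per-reaction oracle: sum stoichiometry x evaluate_rate() in
## plain R, never touching the compiled evaluator.
brute_force_rhs <- function(net, state) {
  dx <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  for (rx in net$reactions) {
    v <- evaluate_rate(rx, state, net$params)
    for (i in seq_along(rx$reactants)) {
      sp <- names(rx$reactants)[i]
      dx[sp] <- dx[sp] - rx$reactants[[i]] * v
    }
    for (i in seq_along(rx$products)) {
      sp <- names(rx$products)[i]
      dx[sp] <- dx[sp] + rx$products[[i]] * v
    }
  }
  dx[net$species$clamped[match(names(dx), net$species$name)]] <- 0
  dx
}

## Toy: reversible binding A + B <-> C with no synthesis or degradation.
toy_binding_network <- function(kf = 2, kr = 0.5) {
  build_network(
    data.frame(name = c("A", "B", "C"), compartment = "cytoplasm",
               init = c(1, 0.6, 0)),
    list(reaction("b1", "A binds B", reactants = c(A = 1, B = 1),
                  products = c(C = 1), kf = "kf", kr = "kr")),
    c(kf = kf, kr = kr))
}

## Toy: constant synthesis s and first-order decay d (steady state s/d).
toy_birth_death <- function(s = 2e-3, d = 5e-3) {
  build_network(
    data.frame(name = "X", compartment = "cytoplasm", init = 0),
    list(reaction("syn", "synthesis", products = c(X = 1), kf = "s",
                  factors = list(), tags = "translation"),
         reaction("dec", "decay", reactants = c(X = 1), kf = "d",
                  tags = "degradation")),
    c(s = s, d = d))
}

## Toy mirroring the RISC/mRNA repression equilibrium with clamped RISC:
## free mRNA (clamped) + RISC -> complex (ka), complex -> (kd back, kdeg out).
toy_repression_network <- function(ka = 5, kd = 1e-3, kdeg = 2e-3,
                                   risc = 0.02, mrna = 1e-3) {
  build_network(
    data.frame(name = c("RISC", "mRNA", "cplx"), compartment = "cytoplasm",
               init = c(risc, mrna, 0), clamped = c(TRUE, TRUE, FALSE)),
    list(reaction("rep", "repression", reactants = c(mRNA = 1, RISC = 1),
                  products = c(cplx = 1), kf = "ka", kr = "kd"),
         reaction("dec", "complex decay", reactants = c(cplx = 1), kf = "kdeg",
                  tags = "degradation")),
    c(ka = ka, kd = kd, kdeg = kdeg))
}

## Four-pool linear NFAT-like cycle: P_c -> D_c (d) -> D_n (i) -> P_n (r)
## -> P_c (e), plus D_c -> P_c (b). Closed, total conserved.
toy_nfat_network <- function(d = 0.2, b = 0.5, i = 0.1, r = 0.05, e = 0.1,
                             total = 1) {
  build_network(
    data.frame(name = c("P_c", "D_c", "D_n", "P_n"),
               compartment = c("cytoplasm", "cytoplasm", "nucleus", "nucleus"),
               init = c(total, 0, 0, 0)),
    list(reaction("deph", "dephosphorylation", reactants = c(P_c = 1),
                  products = c(D_c = 1), kf = "d"),
         reaction("reph", "rephosphorylation", reactants = c(D_c = 1),
                  products = c(P_c = 1), kf = "b"),
         reaction("imp", "import", reactants = c(D_c = 1),
                  products = c(D_n = 1), kf = "i"),
         reaction("kin", "nuclear kinase", reactants = c(D_n = 1),
                  products = c(P_n = 1), kf = "r"),
         reaction("exp", "export", reactants = c(P_n = 1),
                  products = c(P_c = 1), kf = "e")),
    c(d = d, b = b, i = i, r = r, e = e))
}

## Closed-form steady state of the 4-pool linear cycle via the null space of
## the rate matrix (independent linear-algebra oracle).
toy_nfat_steady_fraction <- function(d, b, i, r, e, total = 1) {
  A <- matrix(0, 4, 4)  # columns/rows: P_c, D_c, D_n, P_n
  A[1, 1] <- -d; A[1, 2] <- b; A[1, 4] <- e
  A[2, 1] <- d; A[2, 2] <- -(b + i)
  A[3, 2] <- i; A[3, 3] <- -r
  A[4, 3] <- r; A[4, 4] <- -e
  ns <- svd(A)$v[, 4]
  ns <- ns / sum(ns) * total
  stats::setNames(ns, c("P_c", "D_c", "D_n", "P_n"))
}
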