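# Simulation fixtures shared across test files.  Heavy objects are built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# study-scale simulation used for parameter-recovery checks
study34_sim <- function() {
  cached("study34_sim", simulate_study("STUDY34_LIKE", n = 2000, seed = 101))
}

study34_fit3 <- function() {
  cached("study34_fit3", {
    suppressWarnings(red_cfa(study34_sim()$responses,
                             structure = "THREE_FACTOR"))
  })
}

# unidimensional bank with 6 strong (lambda 0.7) and 6 weak (lambda 0.2)
# candidates around the 9-item base; used for screening recovery
screening_sim <- function() {
  cached("screening_sim", {
    ids <- c(paste0("base", 1:9), paste0("hi", 1:6), paste0("lo", 1:6))
    bank <- item_bank(
      id = ids,
      domain = "LOSS_OF_CONTROL",
      n_options = 5L,
      is_reference = c(rep(TRUE, 9), rep(FALSE, 12))
    )
    lam <- setNames(c(rep(0.75, 9), rep(0.7, 6), rep(0.2, 6)), ids)
    shifts <- setNames(seq(-1.2, 1.2, length.out = length(ids)), ids)
    tau <- lapply(shifts, function(s) s + c(-1, -0.35, 0.35, 1))
    model <- generating_model(bank, lam, tau, diag(3), n = 2000L)
    set.seed(202)
    theta <- simulate_latent(2000L, diag(3))
    list(bank = bank,
         responses = simulate_responses(theta, model),
         model = model, latent = theta)
  })
}

screening_result <- function() {
  cached("screening_result", {
    s <- screening_sim()
    base <- s$bank$id[s$bank$is_reference]
    screen_candidates(base, setdiff(s$bank$id, base), s$responses)
  })
}

# engineered closure scenario: reference thresholds confined to
# [-0.5, 1.5], candidate thresholds in [-2.5, -1]
closure_sim <- function() {
  cached("closure_sim", {
    ids <- c(paste0("ref", 1:9), paste0("low", 1:3))
    bank <- item_bank(id = ids, domain = "LOSS_OF_CONTROL", n_options = 4L,
                      is_reference = c(rep(TRUE, 9), rep(FALSE, 3)))
    ref_shift <- seq(0.05, 0.95, length.out = 9)
    tau <- c(lapply(ref_shift, function(s) s + c(-0.45, 0, 0.45)),
             lapply(c(-1.9, -1.8, -1.7), function(s) s + c(-0.35, 0, 0.35)))
    names(tau) <- ids
    lam <- setNames(rep(0.75, 12), ids)
    model <- generating_model(bank, lam, tau, diag(3), n = 1500L)
    set.seed(303)
    theta <- simulate_latent(1500L, diag(3))
    list(bank = bank, responses = simulate_responses(theta, model),
         model = model)
  })
}

# hand-built selection fixtures (<= 10 candidates, <= 6 gaps) exercising
# the greedy policy and its tie-breaks; each entry: gaps_covered (named
# list), domains, severities, reference_domains, n_gaps
selection_fixtures <- function() {
  ex <- refinement_example()
  list(
    chain = list(
      gaps_covered = list(A = c(1L, 2L), B = 2L, C = 3L, D = 4L),
      domains = c(A = "LOSS_OF_CONTROL", B = "PREOCCUPATION",
                  C = "LACK_OF_SATIETY", D = "PREOCCUPATION"),
      severity = c(A = -1, B = 0, C = 0.5, D = 1),
      reference_domains = character(0), n_gaps = 4L),
    single_covers_all = list(
      gaps_covered = list(A = 1:3, B = 1L, C = 2L),
      domains = c(A = "LOSS_OF_CONTROL", B = "LOSS_OF_CONTROL",
                  C = "PREOCCUPATION"),
      severity = c(A = 0, B = -1, C = 1),
      reference_domains = character(0), n_gaps = 3L),
    identical_twins = list(
      gaps_covered = list(B = 1L, A = 1L),
      domains = c(B = "PREOCCUPATION", A = "PREOCCUPATION"),
      severity = c(B = 0.3, A = 0.3),
      reference_domains = character(0), n_gaps = 1L),
    domain_balance = list(
      gaps_covered = list(loc1 = 1L, sat1 = 1L, po1 = 2L),
      domains = c(loc1 = "LOSS_OF_CONTROL", sat1 = "LACK_OF_SATIETY",
                  po1 = "PREOCCUPATION"),
      severity = c(loc1 = 0, sat1 = 0, po1 = 0),
      reference_domains = c(rep("LOSS_OF_CONTROL", 4),
                            rep("LACK_OF_SATIETY", 1),
                            rep("PREOCCUPATION", 2)),
      n_gaps = 2L),
    uncoverable_gap = list(
      gaps_covered = list(A = 1L, B = 2L),
      domains = c(A = "LOSS_OF_CONTROL", B = "PREOCCUPATION"),
      severity = c(A = 0, B = 0),
      reference_domains = character(0), n_gaps = 3L),
    published = list(
      gaps_covered = setNames(ex$audit$gaps_covered, ex$audit$id),
      domains = setNames(ex$audit$domain, ex$audit$id),
      severity = setNames(ex$audit$mean_threshold, ex$audit$id),
      reference_domains = ex$reference_domains, n_gaps = ex$n_gaps)
  )
}

as_audit <- function(fx) {
  out <- data.frame(id = names(fx$gaps_covered),
                    domain = unname(fx$domains[names(fx$gaps_covered)]),
                    mean_threshold = unname(fx$severity[names(fx$gaps_covered)]),
                    stringsAsFactors = FALSE)
  out$gaps_covered <- unname(fx$gaps_covered)
  out$n_gaps <- lengths(fx$gaps_covered)
  out$retained <- out$n_gaps > 0L
  out
}
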