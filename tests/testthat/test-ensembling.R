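test_that("filtering keeps only MCC-positive soldiers above epsilon, ranked", {
  y <- rep(c(1L, 0L), 5)
  good <- stub_soldier(y, y, "perfect")                    # rho 1
  ok <- stub_soldier(c(0L, y[-1]), y, "one_error")         # rho < 1
  bad <- stub_soldier(1L - y, y, "inverted")               # mcc -1
  coin <- stub_soldier(rep(c(1L, 1L, 0L, 0L), length.out = 10), y, "coin")

  none <- filter_successful(list(bad), fraction = 0.33)
  expect_length(none, 0)

  all_kept <- filter_successful(list(ok, good), epsilon = 0)
  expect_equal(sapply(all_kept, `[[`, "family"), c("perfect", "one_error"))

  # ordering matches an independent sort on (rho, mcc, accuracy)
  pool <- list(ok, coin, good)
  ranked <- filter_successful(pool, epsilon = -1)
  rhos <- sapply(pool, function(s) s$selection_eval$rho)
  keep <- which(sapply(pool, function(s) s$selection_eval$mcc) > 0)
  expect_equal(sapply(ranked, function(s) s$selection_eval$rho),
               sort(rhos[keep], decreasing = TRUE))
})

test_that("majority vote is modal with the top-rho member breaking ties", {
  votes <- rbind(c(1, 0), c(1, 0), c(0, 0))
  expect_equal(majority_vote(votes, c(0.5, 0.4, 0.3)), c(1L, 0L))
  one <- matrix(c(1, 0, 1), 1)
  expect_equal(majority_vote(one, 0.7), c(1L, 0L, 1L))
  disagree <- rbind(c(1, 1), c(0, 0))
  expect_equal(majority_vote(disagree, c(0.9, 0.5)), c(1L, 1L))
  expect_equal(majority_vote(disagree, c(0.5, 0.9)), c(0L, 0L))
  # duplicating every member never changes the outcome
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(rbinom(15, 1, 0.5), 3, 5)
    r <- runif(3)
    expect_equal(majority_vote(rbind(m, m), c(r, r)), majority_vote(m, r))
  }
})

# Hand-built vote dynamics on 10 samples (checked against manual tallies):
# y = 1,1,1,1,1,0,0,0,0,0
# m1 errs {s5};       rho highest -> seeds the ensemble
# m2 errs {s4,s10};   pairwise ties resolve to m1 -> kept at equal rho
# m3 errs {s4,s5,s10}; 3-member majority errs {s4,s5,s10} -> rejected
# m4 errs {s5,s6,s7,s8}; majority errs {s5} again -> kept
greedy_fixture <- function() {
  y <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  m1 <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  m2 <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L)
  m3 <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L)
  m4 <- c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 0L)
  list(y = y,
       soldiers = list(stub_soldier(m1, y, "m1"), stub_soldier(m2, y, "m2"),
                       stub_soldier(m3, y, "m3"), stub_soldier(m4, y, "m4")))
}

test_that("greedy construction rejects deteriorating members and recovers", {
  fx <- greedy_fixture()
  ranked <- filter_successful(fx$soldiers, epsilon = 0)
  expect_equal(sapply(ranked, `[[`, "family"), c("m1", "m2", "m3", "m4"))
  ens <- build_greedy_ensemble(ranked, fx$y)
  expect_equal(sapply(ens$members, `[[`, "family"), c("m1", "m2", "m4"))
  # manual tally: final majority errs only on s5 -> accuracy 0.9
  expect_equal(ens$selection_eval$accuracy, 0.9)
  expect_true(all(diff(ens$rho_trajectory) >= 0))
  expect_gte(ens$selection_eval$rho, ranked[[1]]$selection_eval$rho)

  single <- build_greedy_ensemble(ranked[1], fx$y)
  expect_equal(single$selection_eval$rho, ranked[[1]]$selection_eval$rho)
  expect_error(build_greedy_ensemble(list(), fx$y), "no successful")
})

test_that("identical perfect members are all kept at constant rho 1", {
  y <- rep(c(1L, 0L), 6)
  trio <- replicate(3, stub_soldier(y, y), simplify = FALSE)
  ens <- build_greedy_ensemble(trio, y)
  expect_length(ens$members, 3)
  expect_equal(ens$rho_trajectory, rep(1, 3))
})

test_that("final strategies behave per contract and (c) can beat (a)", {
  fx <- greedy_fixture()
  y <- fx$y
  lig <- filter_successful(fx$soldiers[1:2], epsilon = 0)
  ft <- filter_successful(fx$soldiers[3], epsilon = 0)

  a <- build_final_ensemble(lig, ft, y, strategy = "a")
  expect_equal(sort(sapply(a$members, `[[`, "family")), c("m1", "m2", "m3"))
  # union admits m3, whose vote damage drops accuracy to 0.7
  expect_equal(a$selection_eval$accuracy, 0.7)

  cc <- build_final_ensemble(lig, ft, y, strategy = "c")
  expect_equal(sapply(cc$members, `[[`, "family"), c("m1", "m2"))
  expect_gt(cc$selection_eval$rho, a$selection_eval$rho)

  b <- build_final_ensemble(lig, ft, y, strategy = "b")
  expect_s3_class(b, "ito_ensemble")
  expect_true(all(diff(b$rho_trajectory) >= 0))

  # empty FT list degenerates to the LIG greedy ensemble
  solo <- build_final_ensemble(lig, list(), y, strategy = "c")
  lig_ens <- build_greedy_ensemble(lig, y)
  expect_equal(sapply(solo$members, `[[`, "family"),
               sapply(lig_ens$members, `[[`, "family"))
  expect_equal(solo$selection_eval, lig_ens$selection_eval)
  expect_error(build_final_ensemble(list(), list(), y), "empty")
})

test_that("the ensemble never scores below its best member on selection data", {
  set.seed(77)
  for (rep in 1:25) {
    n <- 14
    y <- c(rep(1L, 7), rep(0L, 7))
    pool <- lapply(1:5, function(i) {
      noise <- rbinom(n, 1, 0.25)
      stub_soldier(as.integer(xor(y, noise)), y, paste0("r", i))
    })
    ranked <- filter_successful(pool, fraction = 0.5)
    if (length(ranked) == 0) next
    ens <- build_greedy_ensemble(ranked, y)
    best <- max(sapply(ranked, function(s) s$selection_eval$rho))
    expect_gte(ens$selection_eval$rho + 1e-12, best)
    expect_true(all(diff(ens$rho_trajectory) >= -1e-12))
  }
})
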