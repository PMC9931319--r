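test_that("Fisher-z test tracks d-separation in chains and colliders", {
  set.seed(40)
  n <- 10000
  k <- rnorm(n)
  # chain x -> k -> y
  xc <- 0.8 * rnorm(n)
  kc <- 0.7 * xc + rnorm(n)
  yc <- 0.7 * kc + rnorm(n)
  chain <- cbind(x = xc, k = kc, y = yc)
  expect_false(ci_test(chain, "x", "y")$independent)
  expect_true(ci_test(chain, "x", "y", "k")$independent)
  # collider x -> k <- y
  xx <- rnorm(n)
  yy <- rnorm(n)
  kk <- 0.7 * xx + 0.7 * yy + rnorm(n)
  coll <- cbind(x = xx, k = kk, y = yy)
  expect_true(ci_test(coll, "x", "y")$independent)
  expect_false(ci_test(coll, "x", "y", "k")$independent)
  expect_error(ci_test(coll, "x", "y", "x"), "exclude")
})

test_that("Fisher-z null rejection rate sits at the nominal level", {
  set.seed(41)
  rejections <- vapply(1:400, function(r) {
    d <- matrix(rnorm(200 * 3), 200, dimnames = list(NULL, c("a", "b", "c")))
    !ci_test(d, "a", "b", "c", alpha = 0.05)$independent
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("degenerate conditioning returns dependence with a flag", {
  d <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8),
             b = c(2, 1, 4, 3, 6, 5, 8, 7),
             c = c(1, 1, 1, 1, 1, 1, 1, 1)) # constant: singular
  res <- ci_test(d, "a", "b", "c")
  expect_true(res$degenerate)
  expect_false(res$independent)
})

test_that("oracle FCI reproduces textbook structures", {
  # fully independent variables: edgeless PAG
  d0 <- causal_dag(c("a", "b", "c"), tibble::tibble(from = character(0),
                                                    to = character(0)))
  expect_equal(nrow(pag_edges(fci(d0))), 0)
  # collider orients both arrowheads
  dcol <- causal_dag(c("x", "k", "y"),
                     tibble::tibble(from = c("x", "y"), to = c("k", "k")))
  pcol <- fci(dcol)
  e <- pag_edges(pcol)
  expect_equal(sort(e$mark_b[e$node_b == "k"], decreasing = TRUE),
               sort(rep("arrow", sum(e$node_b == "k")), decreasing = TRUE))
  # latent confounder: bidirected marks between X and Y
  dlat <- causal_dag(c("A", "B", "X", "Y", "L"),
                     tibble::tibble(from = c("A", "B", "L", "L"),
                                    to = c("X", "Y", "X", "Y")))
  plat <- fci(dlat, observed = c("A", "B", "X", "Y"))
  e2 <- pag_edges(plat)
  xy <- e2[e2$node_a == "X" & e2$node_b == "Y", ]
  expect_equal(nrow(xy), 1)
  expect_equal(xy$mark_a, "arrow")
  expect_equal(xy$mark_b, "arrow")
  # exact reproducibility of the oracle run
  expect_identical(fci(dlat, observed = c("A", "B", "X", "Y"))$amat, plat$amat)
})

test_that("oracle FCI recovers the skeleton of random latent-free DAGs", {
  for (s in 1:15) {
    g <- random_dag(6, prob = 0.3, seed = s)
    pg <- fci(g, max_cond_size = 5)
    expect_identical(unname(pg$amat != 0), unname(g$amat | t(g$amat)),
                     label = paste("skeleton, seed", s))
  }
})

test_that("Fisher-z FCI output is invariant to row order", {
  set.seed(42)
  g <- random_dag(5, prob = 0.35, seed = 11)
  d <- simulate_dag_data(g, n = 5000, coef = 0.7, seed = 3)
  p1 <- fci(as.matrix(d))
  p2 <- fci(as.matrix(d)[sample(nrow(d)), ])
  expect_identical(p1$amat, p2$amat)
})

test_that("JCI pooling encodes indicators and round-trips environments", {
  cfg <- default_scenario(n_hospitals = 2, stays_per_hospital = 100, seed = 9)
  cohort <- sample_cohort(cfg)
  pooled <- build_jci_dataset(cohort)
  expect_equal(nrow(pooled), 200)
  expect_setequal(unique(pooled$hospital_id), c(1, 2))
  expect_true(all(pooled$race_group %in% 0:1))
  expect_true("mortality" %in% names(pooled))
  # splitting the pooled table by the indicator recovers the originals
  split_back <- split(pooled, pooled$hospital_id)
  expect_equal(nrow(split_back[[1]]), sum(cohort$hospital_id == "h01"))
  expect_equal(split_back[[2]]$age, cohort$age[cohort$hospital_id == "h02"])
  expect_error(build_jci_dataset(cohort, indicators = "nope"), "indicator")
})

test_that("JCI knowledge constraints are never violated in the output", {
  cohort <- sample_cohort(default_scenario(stays_per_hospital = 400, seed = 10))
  att <- attribute_shifts(cohort, max_cond_size = 2)
  pag <- att$pag
  env <- c("hospital_id", "region", "beds_band", "teaching")
  for (ctx in c(env, "race_group")) {
    i <- match(ctx, pag$nodes)
    # no arrowheads into any context indicator, except hospital -> race etc.
    incoming <- which(pag$amat[, i] == 2L)
    expect_true(all(pag$nodes[incoming] %in% "hospital_id"),
                label = paste("arrowheads into", ctx))
  }
  # contexts mutually non-adjacent except the declared hospital attributes
  for (a in env[-1]) {
    for (b in setdiff(env[-1], a)) {
      expect_equal(pag$amat[match(a, pag$nodes), match(b, pag$nodes)], 0L)
    }
  }
})

test_that("direct shift summaries report adjacency and drop mediated features", {
  cfg <- default_scenario()
  truth <- ground_truth_graph(cfg)
  knowledge <- jci_knowledge(truth$nodes)
  pag <- fci(truth, max_cond_size = 3, knowledge = knowledge)
  summ <- direct_shift_summary(pag)
  truth_ctx <- truth$edges[truth$edges$from %in%
                             c("hospital_id", "region", "beds_band",
                               "teaching", "race_group"), ]
  # the oracle recovers the hospital row exactly (age, race, 3 vitals, 3 labs)
  hosp_found <- summ$variable[summ$indicator == "hospital_id"]
  hosp_true <- setdiff(truth_ctx$to[truth_ctx$from == "hospital_id"],
                       c("region", "beds_band", "teaching"))
  expect_setequal(hosp_found, hosp_true)
  expect_true("race_group" %in% hosp_found)
  expect_setequal(setdiff(hosp_found, c("race_group", "mortality")),
                  c("age", "temp", "gcs", "urineoutput",
                    "bun", "wbc", "sodium"))
  # mediated-only features are absent: hr shifts only via temp
  expect_false("hr" %in% hosp_found)
  # race row: 4 vitals, 4 labs, elective surgery (plus the outcome edge)
  race_found <- summ$variable[summ$indicator == "race_group"]
  expect_setequal(setdiff(race_found, "mortality"),
                  c("hr", "sysbp", "temp", "pao2fio2",
                    "bun", "potassium", "bicarbonate", "bilirubin",
                    "elective_surgery"))
  # empty PAG gives empty sets
  d0 <- causal_dag(c("hospital_id", "x"), tibble::tibble(from = character(0),
                                                         to = character(0)))
  p0 <- fci(d0)
  expect_equal(nrow(direct_shift_summary(p0, indicators = "hospital_id")), 0)
  expect_error(direct_shift_summary(p0, indicators = "region"), "not in")
})

test_that("PAG edges serialize to the edge-list text format", {
  dcol <- causal_dag(c("x", "k", "y"),
                     tibble::tibble(from = c("x", "y"), to = c("k", "k")))
  pag <- fci(dcol)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pag(pag, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("node_a", "mark_a", "mark_b", "node_b"))
  expect_equal(nrow(back), 2)
  expect_true(all(back$mark_b %in% c("circle", "arrow", "tail")))
})
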