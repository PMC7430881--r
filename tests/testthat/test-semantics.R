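# Semantic values under the three models and disease semantic similarity.

test_that("plain-decay profiles match the hand recursion on the toy chain", {
  v <- toy_v0()
  p <- sv_lncsim1(build_dag(v, "A"))
  expect_equal(p$contrib[c("A", "X", "R")], c(A = 1, X = 0.5, R = 0.25))
  expect_equal(p$total, 1.75)

  root <- sv_lncsim1(build_dag(v, "R"))
  expect_equal(root$contrib, c(R = 1))
  expect_equal(root$total, 1)

  nodecay <- sv_lncsim1(build_dag(v, "A"), semantic_params("lncsim1",
                                                           delta = 1))
  expect_true(all(nodecay$contrib == 1))
  expect_equal(nodecay$total, 3)
})

test_that("information-content values follow -log(Dags/D)", {
  cnt <- corpus_counts(toy_v0())
  expect_equal(ic_value("A", cnt), -log(1 / 4), tolerance = 1e-12)
  expect_equal(ic_value("R", cnt), 0)   # Dags = D: no information
  expect_equal(ic_value("A", cnt, semantic_params("lncsim2", log_base = 2)),
               2)
  expect_error(ic_value("zzz", cnt), "absent")
})

test_that("the IC contribution factor is (max_dags - Dags)/D and monotone", {
  cnt <- corpus_counts(toy_v0())
  expect_equal(ic_contribution_factor(c("R", "X", "A", "B"), cnt),
               c(0, 0.5, 0.75, 0.75))
  # the most frequent term earns no bonus; the factor decreases in Dags
  ord <- order(cnt$dags_count)
  expect_true(all(diff(ic_contribution_factor(names(cnt$dags_count)[ord],
                                              cnt)) <= 0))
})

test_that("IDSSIM profiles match the hand recursion on the toy vocabulary", {
  v <- toy_v0()
  cnt <- corpus_counts(v)
  pa <- sv_idssim(build_dag(v, "A"), cnt)
  expect_equal(pa$contrib[c("A", "X", "R")], c(A = 1, X = 1, R = 0.5))
  expect_equal(pa$total, 2.5)
  pb <- sv_idssim(build_dag(v, "B"), cnt)
  expect_equal(pb$contrib[c("B", "R")], c(B = 1, R = 0.5))
  expect_equal(pb$total, 1.5)
  expect_equal(dss(pa, pb), 0.25)
  expect_equal(dss(pa, pa), 1)
})

test_that("IDSSIM reduces to plain decay when every count is maximal", {
  v <- synth_vocab(n_terms = 15, seed = 3)
  cnt <- corpus_counts(v)
  flat <- structure(list(D = cnt$D,
                         dags_count = setNames(rep(cnt$D, cnt$D),
                                               names(cnt$dags_count)),
                         max_dags = cnt$D),
                    class = "corpus_counts")
  for (d in v$terms) {
    dag <- build_dag(v, d)
    expect_equal(sv_idssim(dag, flat)$contrib, sv_lncsim1(dag)$contrib)
  }
})

test_that("similarity is zero without shared terms and errors across models", {
  v <- mesh_vocab(list(A = "C01.100", B = "D02.200"))
  cnt <- corpus_counts(v)
  pa <- sv_idssim(build_dag(v, "A"), cnt)
  pb <- sv_idssim(build_dag(v, "B"), cnt)
  expect_equal(dss(pa, pb), 0)
  expect_error(dss(pa, sv_lncsim1(build_dag(v, "B"))), "different models")
})

test_that("dss_matrix is symmetric, unit-diagonal and permutation-stable", {
  v <- toy_v0()
  m <- dss_matrix(v, c("A", "B"))
  expect_equal(m, matrix(c(1, 0.25, 0.25, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(dss_matrix(v, "A"), matrix(1, 1, 1,
                                          dimnames = list("A", "A")))
  m4 <- dss_matrix(v, v$terms)
  perm <- c("B", "R", "A", "X")
  expect_equal(dss_matrix(v, perm), m4[perm, perm])
  expect_error(dss_matrix(v, c("A", "nope")), "not in vocabulary")
})

test_that("profiles match the memo-free oracle on random vocabularies", {
  for (seed in 1:25) {
    v <- synth_vocab(n_terms = sample(5:30, 1), n_roots = sample(1:3, 1),
                     depth = 5, branching = 2, seed = seed)
    cnt <- corpus_counts(v)
    delta <- idssim:::with_seed(seed, runif(1, 0.2, 1))
    for (d in sample(v$terms, min(4, length(v$terms)))) {
      dag <- build_dag(v, d)
      p1 <- sv_lncsim1(dag, semantic_params("lncsim1", delta))
      o1 <- oracle_sv(v, d, "lncsim1", delta)
      expect_equal(p1$contrib[sort(names(p1$contrib))],
                   o1[sort(names(o1))], tolerance = 1e-12)
      p3 <- sv_idssim(dag, cnt, semantic_params("idssim", delta))
      o3 <- oracle_sv(v, d, "idssim", delta)
      expect_equal(p3$contrib[sort(names(p3$contrib))],
                   o3[sort(names(o3))], tolerance = 1e-12)
      p2 <- sv_lncsim2(dag, cnt)
      o2 <- oracle_sv(v, d, "lncsim2")
      expect_equal(p2$contrib[sort(names(p2$contrib))],
                   o2[sort(names(o2))], tolerance = 1e-12)
    }
  }
})

test_that("similarity stays within [0, 1] on random vocabularies", {
  for (seed in 1:10) {
    v <- synth_vocab(n_terms = 20, seed = seed)
    for (model in c("idssim", "lncsim1", "lncsim2")) {
      m <- dss_matrix(v, sample(v$terms, 6), semantic_params(model))
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(m, t(m))
    }
  }
})

test_that("rarer terms at the same layer contribute more under IDSSIM", {
  # disease Z sees both branch terms P (rare) and Q (common, many other
  # descendants) at layer 1, each linking straight down to Z
  v <- mesh_vocab(list(R = "C01", P = "C01.100", Q = "C01.200",
                       Z = c("C01.100.001", "C01.200.001"),
                       E1 = "C01.200.010", E2 = "C01.200.020",
                       E3 = "C01.200.030"))
  cnt <- corpus_counts(v)
  expect_lt(cnt$dags_count[["P"]], cnt$dags_count[["Q"]])
  p <- sv_idssim(build_dag(v, "Z"), cnt)
  expect_gt(p$contrib[["P"]], p$contrib[["Q"]])
  # under plain decay the two are indistinguishable
  p1 <- sv_lncsim1(build_dag(v, "Z"))
  expect_equal(p1$contrib[["P"]], p1$contrib[["Q"]])
})

test_that("the alternative child-indexed factor reading is available", {
  v <- toy_v0()
  cnt <- corpus_counts(v)
  p <- sv_idssim(build_dag(v, "A"), cnt,
                 semantic_params("idssim", p_on_child = TRUE))
  # contrib(X) = (delta + P_A) * 1 = 1.25; contrib(R) = (delta + P_X) * 1.25
  expect_equal(p$contrib[c("A", "X", "R")], c(A = 1, X = 1.25, R = 1.25))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(semantic_params(delta = 0), "delta")
  expect_error(semantic_params(delta = 1.2), "delta")
  expect_error(semantic_params(log_base = 1), "log_base")
})
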