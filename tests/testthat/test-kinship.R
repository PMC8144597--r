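test_that("kinship and inbreeding match textbook cases", {
  fs <- FIX$fullsib
  # founders unrelated by convention
  expect_equal(kinship(fs, "W1", "W2"), 0)
  # parent-offspring and full-sib kinship with unrelated non-inbred parents
  expect_equal(kinship(fs, "W1", "C1"), 0.25)
  expect_equal(kinship(fs, "C1", "C2"), 0.25)
  # offspring of a full-sib mating
  expect_equal(inbreeding(fs, "X"), c(X = 0.25))
  # offspring of a parent-offspring mating
  expect_equal(inbreeding(FIX$parent_offspring, "X"), c(X = 0.25))
  # founder conventions
  expect_true(all(inbreeding(FIX$founders) == 0))
  expect_error(kinship(fs, "W1", "NOBODY"), "unknown individual")
})

test_that("generation follows the parental-mean-plus-one rule", {
  g <- generation(FIX$g_mix)
  expect_equal(unname(g[c("W1", "W2", "W3")]), c(0, 0, 0))
  expect_equal(unname(g["P"]), 1)   # two wild-born parents
  expect_equal(unname(g["C"]), 1.5) # G0 x G1 pairing
  # unknown parent counts as G0
  up <- mini_ped(id = c("W", "C1", "C2"), sire = c(NA, NA, NA),
                 dam = c(NA, "W", "C1"),
                 birth = c("2000-01-01", "2005-01-01", "2010-01-01"),
                 origin = c("wild", "captive", "captive"))
  expect_equal(unname(generation(up)[c("C1", "C2")]), c(1, 1.5))
})

test_that("wild-born individuals are founders even with recorded parents", {
  p <- mini_ped(id = c("A", "B", "W", "C"),
                sire = c(NA, NA, "A", "W"), dam = c(NA, NA, "B", "B"),
                birth = c("2000-01-01", "2000-01-01", "2005-01-01",
                          "2010-01-01"),
                origin = c("wild", "wild", "wild", "captive"))
  # W is wild-born: its recorded ancestry is zeroed, so kinship(W, B) = 0
  # and C (offspring of W and B) is non-inbred
  expect_equal(unname(generation(p)["W"]), 0)
  expect_equal(kinship(p, "W", "B"), 0)
  expect_equal(unname(inbreeding(p, "C")), 0)
  # with the convention switched off, W is B's offspring again
  expect_equal(kinship(p, "W", "B", wild_as_founder = FALSE), 0.25)
  # f(C) = kinship(W, B) = 0.25 once W's recorded ancestry counts
  expect_equal(unname(inbreeding(p, "C", wild_as_founder = FALSE)), 0.25)
})

test_that("recursive kinship, tabular matrix and core identities agree on random pedigrees", {
  for (seed in c(101, 202, 303)) {
    p <- small_pedigree(seed)
    K <- kinship_matrix(p)
    expect_true(isSymmetric(K))
    f <- inbreeding(p)
    expect_true(all(f >= 0 & f < 1))
    # kinship(i,i) = 0.5 * (1 + f(i)), exactly
    expect_equal(unname(diag(K)), unname(0.5 * (1 + f[rownames(K)])))
    # recursive path agrees with the tabular path
    ids <- sample(p$records$id, 8)
    for (i in ids[1:4]) for (j in ids[5:8])
      expect_equal(kinship(p, i, j), K[i, j], tolerance = 1e-12)
    # generation identity for captive-born individuals
    g <- generation(p)
    r <- p$records
    cap <- which(r$origin == "captive")
    gs <- ifelse(is.na(r$sire[cap]), 0, g[r$sire[cap]])
    gd <- ifelse(is.na(r$dam[cap]), 0, g[r$dam[cap]])
    expect_equal(unname(g[cap]), unname((gs + gd) / 2 + 1), tolerance = 1e-12)
  }
})

test_that("adding an individual without descendants changes no existing value", {
  p <- small_pedigree(7, n_years = 6)
  K1 <- kinship_matrix(p)
  r <- p$records
  extra <- r[1, ]
  extra$id <- "EXTRA"
  extra$sire <- r$id[which(r$sex == "male")[1]]
  extra$dam <- r$id[which(r$sex == "female")[1]]
  extra$origin <- "captive"
  extra$birth_date <- p$current_date
  extra$death_date <- as.Date(NA)
  p2 <- as_pedigree(rbind(r, extra), current_date = p$current_date)
  K2 <- kinship_matrix(p2)
  expect_equal(K2[rownames(K1), colnames(K1)], K1, tolerance = 1e-15)
  expect_equal(inbreeding(p2)[r$id], inbreeding(p)[r$id], tolerance = 1e-15)
})

test_that("gene dropping reproduces recursive kinship within Monte Carlo error", {
  # trivial case: founders give estimate 0 with SE 0
  gd0 <- gene_drop_kinship(FIX$founders, "W1", "W2", replicates = 500, seed = 1)
  expect_equal(gd0$estimate, 0)
  expect_equal(gd0$se, 0)

  # determinism under the seed
  g1 <- gene_drop_kinship(FIX$fullsib, "C1", "C2", replicates = 2000, seed = 9)
  g2 <- gene_drop_kinship(FIX$fullsib, "C1", "C2", replicates = 2000, seed = 9)
  expect_identical(g1$estimate, g2$estimate)

  # full sibs: estimate within 3 SE of 0.25
  g3 <- gene_drop_kinship(FIX$fullsib, "C1", "C2", replicates = 50000, seed = 2)
  expect_lt(abs(g3$estimate - 0.25), 3 * g3$se + 1e-12)

  # oracle equivalence on random pedigrees (reduced scale; the acceptance
  # suite runs the full 10-pedigree x 20-pair x 100k version)
  for (seed in c(11, 22)) {
    p <- small_pedigree(seed, n_years = 8)
    ids <- p$records$id
    set.seed(seed)
    pairs <- cbind(sample(ids, 6, replace = TRUE),
                   sample(ids, 6, replace = TRUE))
    est <- gene_drop_kinship_pairs(p, pairs, replicates = 20000, seed = seed)
    for (k in seq_len(nrow(pairs))) {
      exact <- kinship(p, pairs[k, 1], pairs[k, 2])
      expect_lt(abs(est$estimate[k] - exact), 3 * est$se[k] + 1e-9)
    }
  }
})

test_that("Wright's Ne follows the sex-ratio formula", {
  # equal numbers of breeding males and females: Ne = N
  ids <- c(sprintf("M%d", 1:50), sprintf("F%d", 1:50), sprintf("O%d", 1:100))
  p <- mini_ped(id = ids,
                sire = c(rep(NA, 100), rep(sprintf("M%d", 1:50), 2)),
                dam = c(rep(NA, 100), rep(sprintf("F%d", 1:50), 2)),
                sex = c(rep("male", 50), rep("female", 50),
                        rep("unknown", 100)),
                birth = c(rep("2000-01-01", 100), rep("2005-01-01", 100)),
                origin = c(rep("wild", 100), rep("captive", 100)))
  expect_equal(effective_size(p), 100)

  # unequal sex ratio: Nm=10, Nf=40 -> 32
  p2 <- mini_ped(id = c(sprintf("M%d", 1:10), sprintf("F%d", 1:40),
                        sprintf("O%d", 1:40)),
                 sire = c(rep(NA, 50), rep(sprintf("M%d", 1:10), 4)),
                 dam = c(rep(NA, 50), sprintf("F%d", 1:40)),
                 sex = c(rep("male", 10), rep("female", 40),
                         rep("unknown", 40)),
                 birth = c(rep("2000-01-01", 50), rep("2005-01-01", 40)),
                 origin = c(rep("wild", 50), rep("captive", 40)))
  expect_equal(effective_size(p2), 32)

  # no breeding males -> error
  expect_error(effective_size(FIX$founders), "male")
})
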