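test_that("pedigrees are validated and topologically sorted", {
  ped <- new_pedigree(c("O", "S", "D"), c("S", NA, NA), c("D", NA, NA))
  expect_equal(ped$animal, c("S", "D", "O"))

  expect_error(new_pedigree(c("O", "D"), c("O", NA), c("D", NA)),
               "own parent")
  expect_error(new_pedigree(c("a", "a"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(new_pedigree(c("x", "y"), c("y", "x"), c(NA, NA)), "cycle")

  # shuffled multi-generation chain: parents must precede offspring
  set.seed(3)
  anim <- paste0("g", 1:6)
  sire <- c(NA, "g1", "g2", "g3", "g4", "g5")
  dam <- rep(NA_character_, 6)
  shuffle <- sample(6)
  ped <- new_pedigree(anim[shuffle], sire[shuffle], dam[shuffle])
  pos <- match(ped$animal, ped$animal)
  names(pos) <- ped$animal
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) expect_lt(pos[p], i)
    }
  }
  expect_equal(ped$animal[1], "g1")
})

test_that("pedigree files parse with sentinel codes and either delimiter", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "s,0,", "d,NA,0", "o,s,d"), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire[ped$animal %in% c("s", "d")])))

  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s\t0\t0", "d\t0\t0", "o\ts\td"), path2)
  ped2 <- read_pedigree(path2)
  expect_equal(ped2$animal, c("s", "d", "o"))
})

test_that("inbreeding follows the tabular relationship of the parents", {
  trio <- new_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  expect_equal(unname(inbreeding(trio)), c(0, 0, 0))

  fullsib <- new_pedigree(c("s", "d", "x", "y", "o"),
                          c(NA, NA, "s", "s", "x"),
                          c(NA, NA, "d", "d", "y"))
  expect_equal(unname(inbreeding(fullsib)["o"]), 0.25)

  po <- new_pedigree(c("s", "d", "x", "o"),
                     c(NA, NA, "s", "s"), c(NA, NA, "d", "x"))
  expect_equal(unname(inbreeding(po)["o"]), 0.25)
})

test_that("pairwise relationships match the tabular method", {
  ped <- new_pedigree(c("s", "d", "d2", "o", "h"),
                      c(NA, NA, NA, "s", "s"),
                      c(NA, NA, NA, "d", "d2"))
  expect_equal(relationship(ped, "s", "s"), 1)
  expect_equal(relationship(ped, "s", "o"), 0.5)
  expect_equal(relationship(ped, "o", "h"), 0.25)  # half sibs
  expect_equal(relationship(ped, "o", "h"), relationship(ped, "h", "o"))
  expect_error(relationship(ped, "s", "zz"), "unknown")
})

test_that("the sparse A-inverse inverts the tabular A", {
  single <- new_pedigree("x", NA, NA)
  expect_equal(as.matrix(a_inverse(single)), matrix(1, 1, 1),
               ignore_attr = TRUE)

  trio <- new_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  Ai <- as.matrix(a_inverse(trio))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2))
  expect_equal(Ai["s", "d"], 0.5)
  expect_equal(Ai["s", "o"], -1)

  for (seed in c(11, 12)) {
    for (n in c(60, 200)) {
      ped <- random_pedigree(n, nf = 12, seed = seed + n)
      A <- relationship_matrix(ped)
      Ai <- a_inverse(ped)
      expect_lt(max(abs(as.matrix(Ai %*% A) - diag(n))), 1e-8)
      expect_equal(unname(diag(A)), unname(1 + inbreeding(ped)),
                   tolerance = 1e-12)
      expect_equal(attr(Ai, "logdet_a"),
                   as.numeric(determinant(A)$modulus), tolerance = 1e-8)
    }
  }
})

test_that("relationships stay within their theoretical range", {
  ped <- random_pedigree(80, nf = 8, seed = 21)
  A <- relationship_matrix(ped)
  fmax <- max(inbreeding(ped))
  expect_true(all(A >= 0))
  expect_lte(max(A[upper.tri(A)]), 1 + fmax + 1e-12)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})
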