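make_pheno_file <- function(path, rows) {
  header <- "animal,sire,dam,gender,batch,stable,age_bw2,age_bw7,age_ratio,person,bw2,bw7,ratio"
  writeLines(c(header, rows), path)
}

test_that("phenotype files load, validate, and count trait availability", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_pheno_file(path, c(
    "o1,s1,d1,m,1,1,12,45,46,3,250,2100,27.5",
    "o2,s1,d1,f,1,2,13,46,47,4,240,,",
    "o3,s1,d2,m,2,1,12,45,48,5,255,1900,31.2"))
  ped <- new_pedigree(c("s1", "d1", "d2", "o1", "o2", "o3"),
                      c(NA, NA, NA, "s1", "s1", "s1"),
                      c(NA, NA, NA, "d1", "d1", "d2"))
  tab <- read_phenotypes(path, ped)
  expect_s3_class(tab, "phenotype_table")
  expect_equal(nrow(tab), 3)
  expect_equal(unname(attr(tab, "trait_counts")),
               c(3L, 2L, 2L), ignore_attr = TRUE)

  # out-of-range heart ratio names the row
  path2 <- withr::local_tempfile(fileext = ".csv")
  make_pheno_file(path2, c("o1,s1,d1,m,1,1,12,45,46,3,250,2100,150"))
  expect_error(read_phenotypes(path2), "row")

  # parents must exist in the pedigree when one is supplied
  path3 <- withr::local_tempfile(fileext = ".csv")
  make_pheno_file(path3, c("o1,sX,d1,m,1,1,12,45,46,3,250,2100,27"))
  expect_error(read_phenotypes(path3, ped), "missing from the pedigree")

  # column mapping renames file columns onto the schema
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,gender,batch,stable,age_bw2,age_bw7,age_ratio,person,weight2,bw7,ratio",
               "o1,s1,d1,m,1,1,12,45,46,3,250,2100,27.5"), path4)
  tab4 <- read_phenotypes(path4, col_map = c(animal = "id", bw2 = "weight2"))
  expect_equal(tab4$animal, "o1")
  expect_equal(tab4$bw2, 250)
})

test_that("a missing-cell fraction reduces the trait count accordingly", {
  pop <- pop_small(1)
  ph <- pop$phenotypes
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, path)
  back <- read_phenotypes(path, pop$pedigree)
  expect_equal(attr(back, "trait_counts")[["bw7"]], sum(!is.na(ph$bw7)))
  expect_equal(back$bw7, ph$bw7)
  expect_equal(back$ratio, ph$ratio)
})

test_that("small sire families are removed without touching kept records", {
  base <- data.frame(
    animal = paste0("o", 1:35),
    sire = c(rep("s1", 25), rep("s2", 10)),
    dam = rep(paste0("d", 1:7), each = 5),
    gender = "m", batch = 1, stable = 1,
    age_bw2 = 12, age_bw7 = 45, age_ratio = 46, person = 1,
    bw2 = stats::rnorm(35, 250, 10), bw7 = stats::rnorm(35, 2000, 100),
    ratio = stats::runif(35, 20, 40))
  tab <- as_phenotypes(base)
  kept <- filter_small_sire_families(tab, 20)
  expect_equal(nrow(kept), 25)
  expect_equal(attr(kept, "dropped_sires"), "s2")
  expect_equal(as.data.frame(kept)[c("animal", "bw2", "bw7")],
               as.data.frame(tab[tab$sire == "s1", c("animal", "bw2", "bw7")]),
               ignore_attr = TRUE)
  expect_equal(nrow(filter_small_sire_families(tab, 0)), 35)
})

test_that("sire-family filtering reproduces the generator bookkeeping", {
  pop <- pop_small(3)
  counts <- table(pop$phenotypes$sire)
  thr <- as.integer(stats::quantile(counts, 0.2))
  kept <- filter_small_sire_families(pop$phenotypes, thr)
  expect_equal(length(unique(kept$sire)), sum(counts >= thr))
  expect_equal(nrow(kept), sum(counts[counts >= thr]))
})

test_that("variance reports round-trip through text files", {
  hs <- halfsib_data(ns = 15, np = 8)
  fit <- reml_fit(mixed_design(hs$y, random = list(
    list(name = "sire", id = hs$sire, structure = "iid"))), se = "hessian")
  dir <- withr::local_tempdir()
  write_variance_report(fit, dir, "hs")
  back <- read_variance_report(dir, "hs")
  expect_equal(back$components$estimate, unname(fit$components),
               tolerance = 1e-13)
  expect_equal(back$summary[["logL"]], fit$logL, tolerance = 1e-13)
  expect_equal(back$summary[["n_records"]], fit$n_records)
  sols <- back$solutions
  expect_equal(sols$value[sols$term == "sire"],
               unname(fit$ranef$sire[, 1]), tolerance = 1e-13)
})

test_that("tolerance-model reports carry one row per residual class", {
  fit <- fit3_small(1)
  dir <- withr::local_tempdir()
  write_variance_report(fit, dir, "tol")
  back <- read_variance_report(dir, "tol")
  expect_equal(sum(grepl("^residual\\.class", back$components$component)), 5)
})

test_that("empty trajectory tables write a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(ratioplat = numeric(0), v_g = numeric(0))
  write_trajectory(empty, path)
  expect_equal(length(readLines(path)), 1L)

  g <- table1_g_block()
  ts <- trajectory_ratios(g, gencov2(2771, 23, 0), rep(5e4, 5))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(ts, path2)
  got <- utils::read.csv(path2)
  expect_equal(nrow(got), nrow(ts$trajectory))
  expect_true(file.exists(sub("\\.csv$", "_cv.csv", path2)))
})
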