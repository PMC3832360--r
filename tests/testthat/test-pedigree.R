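test_that("read_pedigree parses both dialects and preserves order", {
  linkage <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 fa 0 0 1", "F1 mo 0 0 2", "F1 ch fa mo 2"), linkage)
  ped <- read_pedigree(linkage, dialect = "linkage")
  expect_s3_class(ped, "fam_pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$individual_id, c("fa", "mo", "ch"))
  expect_equal(ped$founder, c(TRUE, TRUE, FALSE))
  expect_equal(ped$sex, c("male", "female", "female"))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family,id,father,mother,sex",
               "F1,fa,0,0,1", "F1,mo,,,2", "F1,ch,fa,mo,2"), csv)
  ped2 <- read_pedigree(csv, dialect = "csv")
  expect_equal(ped2$father_id, ped$father_id)
  expect_equal(ped2$founder, ped$founder)
})

test_that("structural defects are rejected", {
  # self-parenthood (cycle of length 1)
  bad <- ped_trio()
  bad$sex[3] <- "male"
  bad$father_id[3] <- bad$individual_id[3]
  expect_error(as_pedigree(bad), "cycle")
  # longer cycle
  cyc <- tibble::tibble(
    family_id = "F1", individual_id = c("a", "b"),
    father_id = c("b", "a"), mother_id = c(NA, NA), sex = c("male", "male")
  )
  expect_error(as_pedigree(cyc), "cycle")
  # duplicate id within family
  dup <- dplyr::bind_rows(ped_trio(), ped_trio()[3, ])
  expect_error(as_pedigree(dup), "duplicate")
  # father recorded female
  conf <- ped_trio()
  conf$sex[1] <- "female"
  expect_error(as_pedigree(conf), "father")
  # parent id referencing another family
  cross <- dplyr::bind_rows(ped_trio("F1"), ped_trio("F2"))
  cross$father_id[6] <- "F1_fa"
  expect_error(as_pedigree(cross), "not found in family")
  # unknown sex for a non-founder
  unk <- ped_trio()
  unk$sex[3] <- "0"
  expect_error(as_pedigree(unk), "non-founders")
  # unknown sex founder is fine by default but not in strict mode
  unk2 <- ped_trio()[1:2, ]
  unk2$sex[1] <- "0"
  expect_silent(as_pedigree(unk2))
  expect_error(as_pedigree(unk2, strict_sex = TRUE), "strict")
})

test_that("a simulated study roster round-trips through the CSV dialect", {
  set.seed(8)
  ped <- simulate_pedigrees(sim_config(n_families = 50))
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- ped
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  readr::write_csv(dplyr::transmute(out, family = family_id, id = individual_id,
                                    father = father_id, mother = mother_id,
                                    sex = sex), csv)
  back <- read_pedigree(csv, dialect = "csv")
  expect_equal(back$individual_id, ped$individual_id)
  expect_equal(back$father_id, ped$father_id)
  expect_equal(back$founder, ped$founder)
})

test_that("kinship matrix gives textbook relationships", {
  ped <- ped_nuclear(1, k = 2)
  A <- kinship_matrix(ped)
  ids <- ped$individual_id
  expect_equal(unname(diag(A)), rep(1, 4))
  expect_equal(A[ids[1], ids[3]], 0.5)  # parent-offspring
  expect_equal(A[ids[3], ids[4]], 0.5)  # full sibs
  expect_equal(A[ids[1], ids[2]], 0)    # unrelated mates

  half <- tibble::tibble(
    family_id = "H1",
    individual_id = c("fa", "mo1", "mo2", "c1", "c2"),
    father_id = c(NA, NA, NA, "fa", "fa"),
    mother_id = c(NA, NA, NA, "mo1", "mo2"),
    sex = c("male", "female", "female", "male", "female")
  )
  H <- kinship_matrix(as_pedigree(half))
  expect_equal(H["c1", "c2"], 0.25)     # half sibs
})

test_that("kinship agrees with exact transmission enumeration, including inbreeding", {
  for (ped in list(ped_trio(), ped_nuclear(1, 3), ped_consanguineous())) {
    A <- kinship_matrix(as_pedigree(ped))
    O <- oracle_kinship_enum(ped)
    expect_equal(A, O[rownames(A), colnames(A)], tolerance = 1e-12)
  }
  # the inbred child of a half-sib mating has f = 1/8
  A <- kinship_matrix(as_pedigree(ped_consanguineous()))
  expect_equal(A["in1", "in1"], 1 + 1 / 8)
})

test_that("kinship is symmetric, block-diagonal, bounded, and permutation-consistent", {
  set.seed(3)
  ped <- simulate_pedigrees(sim_config(n_families = 8))
  A <- kinship_matrix(ped)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0 & A <= 2))
  for (f1 in unique(ped$family_id)) for (f2 in setdiff(unique(ped$family_id), f1)) {
    expect_true(all(A[ped$individual_id[ped$family_id == f1],
                      ped$individual_id[ped$family_id == f2]] == 0))
  }
  perm <- sample(nrow(ped))
  A2 <- kinship_matrix(ped[perm, ])
  expect_equal(A2, A[rownames(A2), colnames(A2)])
})

test_that("family_summary reports roles and mean family size", {
  ped <- as_pedigree(ped_trio())
  s <- family_summary(ped)
  expect_equal(s$mean_family_size, 3.0)
  expect_equal(s$fathers, 1)
  expect_equal(s$daughters, 1)

  s0 <- family_summary(ped, phenotyped = character(0))
  expect_equal(s0$n_phenotyped, 0)
  expect_true(is.na(s0$mean_family_size))

  expect_error(family_summary(ped, phenotyped = "ghost"), "absent")
})
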