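test_that("PED round trip resolves links and proband flags", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1 child dad mom 1 1",
               "FAM1 dad 0 0 1 0",
               "FAM1 mom 0 0 2 0"), path)
  ped <- read_ped(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$id[1L], "child")  # index first
  expect_equal(ped$sex, c("male", "male", "female"))

  out <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, out, status = c(1, 0, 1))
  again <- read_ped(out)
  expect_equal(again$id, ped$id)
  expect_equal(again$father_id, ped$father_id)
})

test_that("malformed PED input is rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 kid ghostdad mom 1 1",
               "F1 mom 0 0 2 0"), path)
  expect_error(read_ped(path), "ghostdad")

  path2 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 a 0 0 1 0",
               "F1 b 0 0 2 0"), path2)
  expect_error(read_ped(path2), "proband")
  expect_silent(p <- read_ped(path2, index = "a"))
  expect_equal(p$id[1L], "a")

  expect_error(pedigree(id = c("x", "y"), father_id = c("y", "x"),
                        index = "x"),
               "cyclic")
})

test_that("two-generation PED file matches a hand-built pedigree", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F kid dad mom 2 1",
               "F sib dad mom 1 0",
               "F dad gpa gma 1 0",
               "F mom 0 0 2 0",
               "F gpa 0 0 1 0",
               "F gma 0 0 2 0",
               "F unc gpa gma 1 0",
               "F aun gpa gma 2 0"), path)
  fromfile <- read_ped(path)
  byhand <- pedigree(
    id = c("kid", "sib", "dad", "mom", "gpa", "gma", "unc", "aun"),
    father_id = c("dad", "dad", "gpa", NA, NA, NA, "gpa", "gpa"),
    mother_id = c("mom", "mom", "gma", NA, NA, NA, "gma", "gma"),
    sex = c("female", "male", "male", "female", "male", "female",
            "male", "female"),
    index = "kid")
  A1 <- relationship_matrix(fromfile)
  A2 <- relationship_matrix(byhand)
  expect_equal(A1[byhand$id, byhand$id], A2)
})

test_that("relationship matrix gives textbook coefficients", {
  A <- relationship_matrix(ped_trio())
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A["index", "father"], 0.5)
  expect_equal(A["father", "mother"], 0)

  founders <- pedigree(id = c("a", "b", "c"), index = "a")
  expect_equal(unname(relationship_matrix(founders)), diag(3))

  tg <- ped_three_generation()
  A <- relationship_matrix(tg)
  expect_equal(A["index", "pgf"], 0.25)       # grandparent
  expect_equal(A["index", "pat_au1"], 0.25)   # aunt/uncle
  expect_equal(A["father", "mother"], 0)

  # first cousins: children of two full siblings
  cz <- pedigree(
    id = c("c1", "p1", "s1", "p2", "s2", "gf", "gm", "c2"),
    father_id = c("p1", "gf", NA, "gf", NA, NA, NA, "p2"),
    mother_id = c("s1", "gm", NA, "gm", NA, NA, NA, "s2"),
    index = "c1")
  expect_equal(relationship_matrix(cz)["c1", "c2"], 0.125)
})

test_that("relationship matrix agrees with gene-dropping and is stable under reordering", {
  tg <- ped_three_generation()
  A <- relationship_matrix(tg)
  n_rep <- 2e4
  G <- gene_drop_relationship(tg, n_rep = n_rep)
  for (i in seq_len(nrow(tg))) for (j in seq_len(nrow(tg))) {
    se <- sqrt(max(A[i, j] / 2 * (1 - A[i, j] / 2), 1e-12) / n_rep) * 2
    expect_lt(abs(G[i, j] - A[i, j]), max(3 * se, 0.02))
  }

  # reordering the input rows only permutes A
  shuffled <- pedigree(id = rev(tg$id), father_id = rev(tg$father_id),
                       mother_id = rev(tg$mother_id), sex = rev(tg$sex),
                       index = "index")
  As <- relationship_matrix(shuffled)
  expect_equal(As[rownames(A), colnames(A)], A)
})

test_that("inbred pedigrees are flagged", {
  inb <- pedigree(id = c("kid", "f", "m", "gf", "gm"),
                  father_id = c("f", "gf", "gf", NA, NA),
                  mother_id = c("m", "gm", "gm", NA, NA),
                  index = "kid")
  expect_warning(A <- relationship_matrix(inb), "inbreeding")
  expect_gt(A["kid", "kid"], 1)
})

test_that("sex marginalization removes non-applicable relatives", {
  trio <- ped_trio()
  expect_identical(marginalize_sex(trio, "both"), trio)

  trio_f <- pedigree(id = c("index", "father", "mother"),
                     father_id = c("father", NA, NA),
                     mother_id = c("mother", NA, NA),
                     sex = c("female", "male", "female"), index = "index")
  red <- marginalize_sex(trio_f, "female")
  expect_equal(red$id, c("index", "mother"))
  expect_equal(unname(relationship_matrix(red)),
               matrix(c(1, 0.5, 0.5, 1), 2))

  # male index, female-only disease: must flip first
  expect_error(marginalize_sex(trio, "female"), "flip")
  flipped <- flip_sexes(trio)
  expect_equal(marginalize_sex(flipped, "female")$id, c("index", "father"))
})

test_that("marginalized pedigree gives the same AUC as the explicit reduction", {
  # nuclear family of 5 with 2 brothers; female-only disease keeps
  # index + father? no: keeps index, mother (and drops male relatives)
  fam <- pedigree(id = c("index", "father", "mother", "bro1", "bro2"),
                  father_id = c("father", NA, NA, "father", "father"),
                  mother_id = c("mother", NA, NA, "mother", "mother"),
                  sex = c("female", "male", "female", "male", "male"),
                  index = "index")
  red <- marginalize_sex(fam, "female")
  expect_equal(nrow(red), 2L)

  explicit <- pedigree(id = c("index", "mother"),
                       father_id = c(NA, NA), mother_id = c("mother", NA),
                       sex = "female", index = "index")
  spec <- disease_spec(f = 0.1, h2 = 0.8)
  expect_equal(fh_metrics(spec, red)$auc_complete,
               fh_metrics(spec, explicit)$auc_complete, tolerance = 1e-6)
})

test_that("pattern enumeration is complete, unique, and capped", {
  expect_equal(enumerate_patterns(1L), matrix(0:1, ncol = 1))
  p3 <- enumerate_patterns(ped_trio())
  expect_equal(dim(p3), c(8L, 3L))
  expect_equal(p3[2L, ], c(index = 1L, father = 0L, mother = 0L))

  p12 <- enumerate_patterns(12L)
  expect_equal(nrow(p12), 4096L)
  expect_false(anyDuplicated(p12) > 0)

  expect_error(enumerate_patterns(17L), "cap")
})
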