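write_lines <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

test_that("combined cohort TSVs round-trip with weights and PLINK codes", {
  path <- write_lines(c(
    "FID\tIID\tPHENOTYPE\tPC1\tPC2\tWEIGHT",
    "f1\ts1\t2\t0.1\t-0.2\t1",
    "f2\ts2\t1\t0.3\t0.4\t0.2",
    "f3\ts3\t2\t-0.5\t0.6\t1"), "cohort.tsv")
  co <- read_cohort(path)
  expect_identical(co$ids, c("s1", "s2", "s3"))
  expect_identical(co$phenotype, c("diseased", "healthy", "diseased"))
  expect_equal(co$weights, c(1, 0.2, 1))
  expect_equal(co$coords[2, ], c(PC1 = 0.3, PC2 = 0.4))
  expect_identical(co$fid, c("f1", "f2", "f3"))
})

test_that("eigenvec plus phenotype files join on (FID, IID)", {
  ev <- write_lines(c("f1 s1 0.1 0.2 0.3",
                      "f1 s2 -0.1 0.0 0.5",
                      "f2 s3 0.7 0.8 0.9"), "pcs.eigenvec")
  ph <- write_lines(c("FID IID PHENO", "f1 s1 2", "f2 s3 1", "f1 s2 1"),
                    "pheno.txt")
  co <- read_cohort(ev, ph)
  expect_identical(co$ids, c("s1", "s2", "s3"))  # eigenvec order wins
  expect_identical(co$phenotype, c("diseased", "healthy", "healthy"))
  expect_identical(colnames(co$coords), c("PC1", "PC2", "PC3"))
})

test_that("missing phenotype codes drop subjects; bad input is rejected", {
  ev <- write_lines(c("f1 s1 0.1", "f1 s2 0.2", "f1 s3 0.3"), "p.eigenvec")
  ph <- write_lines(c("f1 s1 2", "f1 s2 -9", "f1 s3 1"), "ph.txt")
  expect_message(co <- read_cohort(ev, ph), "missing phenotype")
  expect_identical(co$ids, c("s1", "s3"))

  dup <- write_lines(c("FID\tIID\tPHENOTYPE\tPC1",
                       "f1\ts1\t2\t0.1", "f1\ts1\t1\t0.2"), "dup.tsv")
  expect_error(read_cohort(dup), "duplicate")
  bad <- write_lines(c("FID\tIID\tPHENOTYPE\tPC1",
                       "f1\ts1\t2\t0.1", "f1\ts2\t1\tnot_a_number"), "bad.tsv")
  expect_error(read_cohort(bad), "non-numeric.*line 2")
  ph2 <- write_lines(c("f1 sX 2"), "ph2.txt")
  ev2 <- write_lines(c("f1 s1 0.1"), "ev2.eigenvec")
  expect_error(read_cohort(ev2, ph2), "same \\(FID, IID\\)")
  expect_error(read_cohort(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("weights files round-trip exactly through write and read", {
  co <- small_structured_cohort(80, seed = 14)
  h <- homogenize(co, homogenization_params(10, 0.2, 0.05))
  path <- file.path(withr::local_tempdir(), "weights.tsv")
  write_weights(h, path)
  w <- read_weights(path)
  expect_identical(unname(w[co$ids]), unname(h$final_weights[co$ids]))
  expect_setequal(unique(w), c(1, 0.2))  # knocked subjects carry 0.2
  co2 <- apply_weights(co, w)
  expect_identical(co2$weights, unname(h$final_weights))
  # a cohort writes its current weights the same way
  path2 <- file.path(withr::local_tempdir(), "weights2.tsv")
  write_weights(co2, path2)
  expect_identical(read_weights(path2), w)
})

test_that("PLINK .raw files parse into dosage matrices", {
  raw <- write_lines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G rs3_T",
    "f1 s1 0 0 1 2 0 1 2",
    "f1 s2 0 0 2 1 1 NA 0",
    "f2 s3 0 0 1 2 2 2 1"), "geno.raw")
  g <- read_plink_raw(raw)
  expect_identical(g$subjects, c("s1", "s2", "s3"))
  expect_identical(g$snps, c("rs1_A", "rs2_G", "rs3_T"))
  expect_identical(unname(g$calls[2, ]), c(1, NA, 0))
  expect_identical(attr(g, "phenotype_code"), c(2L, 1L, 2L))
})

test_that("VCF genotypes become ALT-dosage matrices", {
  vcf <- write_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t0/0"), "toy.vcf")
  g <- read_vcf_genotypes(vcf)
  expect_identical(g$subjects, c("s1", "s2", "s3"))
  expect_identical(unname(g$calls[, "rsA"]), c(0, 1, 2))
  expect_identical(unname(g$calls[, "rsB"]), c(1, NA, 0))
})

test_that("eigenvec output feeds straight back into read_cohort", {
  g <- genotype_matrix(
    matrix(c(0, 1, 2, 2, 1, 0, 0, 2, 1, 1, 0, 2, 2, 0, 1, 0, 1, 2, 1, 2,
             0, 1, 2, 0, 1, 2, 1, 0, 2, 1), 10, 3),
    subjects = sprintf("v%02d", 1:10))
  proj <- compute_pcs(g, k = 2)
  dir <- withr::local_tempdir()
  evp <- file.path(dir, "out.eigenvec")
  write_eigenvec(proj, evp)
  php <- file.path(dir, "ph.txt")
  writeLines(paste(proj$subjects, proj$subjects,
                   rep(c(1, 2), 5)), php)
  co <- read_cohort(evp, php)
  expect_identical(co$ids, proj$subjects)
  expect_equal(unname(co$coords), unname(proj$coords), tolerance = 1e-8)
})

test_that("the command-line interface chains the pipeline end to end", {
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "cohort.tsv")
  co <- small_structured_cohort(120, seed = 15)
  df <- as.data.frame(co)
  df$PHENOTYPE <- ifelse(df$phenotype == "diseased", 2L, 1L)
  df$phenotype <- NULL
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)

  expect_identical(homogwas_cli(c("homogenize", "--help")), 0L)
  wpath <- file.path(dir, "weights.tsv")
  jpath <- file.path(dir, "run.json")
  code <- homogwas_cli(c("homogenize", "--cohort", cpath,
                         "--sphere-weight", "15", "--weight-reduction", "0.05",
                         "--out", wpath, "--log-json", jpath))
  expect_identical(code, 0L)
  expect_true(file.exists(wpath) && file.exists(jpath))
  w <- read_weights(wpath)
  expect_identical(sort(unique(unname(w))), c(0.2, 1))

  bpath <- file.path(dir, "bias.json")
  expect_identical(homogwas_cli(c("biastest", "--cohort", cpath,
                                  "--weights", wpath,
                                  "--sphere-weights", "15,30",
                                  "--out", bpath)), 0L)
  rep <- jsonlite::read_json(bpath)
  expect_true(rep$overall > 0 && rep$overall <= 1)

  # user errors exit 1 without raising
  expect_identical(homogwas_cli(c("homogenize", "--cohort",
                                  file.path(dir, "missing.tsv"),
                                  "--out", wpath)), 1L)
  expect_identical(homogwas_cli("frobnicate"), 1L)
  expect_identical(suppressMessages(homogwas_cli(character(0))), 1L)
})
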