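ext <- function(f) system.file("extdata", f, package = "paddynet")

test_that("packaged soil fixture reproduces the printed table", {
  tab1 <- read_soil_table(ext("table1.tsv"))
  expect_s3_class(tab1, "soil_profile_table")
  expect_equal(nrow(tab1), 15)
  expect_equal(tab1$ph[tab1$sample_id == "YX_2"], 6.35)
  expect_equal(tab1$sample_id[1:3], c("YX_1", "YX_2", "YX_3"))
  expect_equal(tab1$ak[tab1$sample_id == "YX_15"], 83.39)
})

test_that("soil table validation enforces texture closure and schema", {
  expect_silent(tab <- read_soil_table(write_tsv_text(soil_lines())))
  expect_equal(tab$sand, 50)
  expect_error(read_soil_table(write_tsv_text(soil_lines(clay = 25))),
               "clay\\+silt\\+sand.*A")
  expect_error(read_soil_table(write_tsv_text(soil_lines(sand = ""))),
               "sand.*row 1")
  no_ph <- sub("\tpH", "\tacidity", soil_lines())
  expect_error(read_soil_table(write_tsv_text(no_ph)), "'ph' not found")
  dup <- c(soil_lines(), paste(c("A", 30, 5.5, 8, 100, 20, 30, 50, 2, 120,
                                 80, 90), collapse = "\t"))
  expect_error(read_soil_table(write_tsv_text(dup)), "duplicated sample_id")
})

test_that("packaged metal fixture reproduces printed cells", {
  tab2 <- suppressWarnings(read_metal_table(ext("table2.tsv")))
  expect_setequal(attr(tab2, "metals"), c("Cd", "Cu", "Pb", "Zn"))
  expect_equal(tab2$total_Cd[tab2$sample_id == "YX_4"], 9.80)
  expect_equal(tab2$total_Cu[tab2$sample_id == "YX_3"], 25.37)
  expect_equal(tab2$dtpa_Cu[tab2$sample_id == "YX_3"], 9.40)
  expect_equal(tab2$pli_reported[tab2$sample_id == "YX_1"], 1.51)
})

test_that("metal table flags DTPA > total as warning, negatives as error", {
  hdr <- "sample_id\tT-Cd\tA-Cd\tT-Cu\tA-Cu\tT-Pb\tA-Pb\tT-Zn\tA-Zn"
  ok <- c(hdr, "A\t1\t1\t2\t2\t3\t3\t4\t4")
  expect_silent(read_metal_table(write_tsv_text(ok)))
  bad <- c(hdr, "A\t1\t2\t2\t2\t3\t3\t4\t4")
  expect_warning(read_metal_table(write_tsv_text(bad)), "DTPA.*Cd")
  neg <- c(hdr, "A\t-1\t0.5\t2\t2\t3\t3\t4\t4")
  expect_error(read_metal_table(write_tsv_text(neg)), "negative")
})

test_that("OTU tables round-trip in both orientations", {
  ot <- otu_table(toy_counts(),
                  taxonomy = setNames(paste0("Bacteria;P", 1:4), paste0("OTU_", 1:4)))
  for (orient in c("taxa_rows", "samples_rows")) {
    f <- tempfile(fileext = ".tsv")
    write_otu_table(ot, f, orientation = orient)
    back <- read_otu_table(f, orientation = orient)
    expect_equal(back$counts, ot$counts)
    expect_equal(sum(back$counts), sum(toy_counts()))
  }
  # taxonomy column survives the taxa-rows round trip
  f <- tempfile(fileext = ".tsv")
  write_otu_table(ot, f)
  expect_equal(read_otu_table(f)$taxonomy, ot$taxonomy)
})

test_that("OTU table contract: integrality, duplicates, all-zero samples", {
  expect_error(otu_table(matrix(c(1.5, 1, 1, 1), 2)), "non-integer")
  m <- toy_counts(); colnames(m) <- c("a", "a", "b", "c")
  expect_error(otu_table(m), "duplicated otu_id")
  z <- toy_counts(); z[2, ] <- 0L
  expect_error(otu_table(z), "all-zero")
  # counts within 1e-6 of integers are accepted
  expect_silent(otu_table(toy_counts() + 1e-8))
})

test_that("numeric tables round-trip to 12 significant digits", {
  tab1 <- read_soil_table(ext("table1.tsv"))
  tab1$som[1] <- pi * 10
  f <- tempfile(fileext = ".tsv")
  write_soil_table(tab1, f)
  back <- read_soil_table(f)
  for (cn in setdiff(names(tab1), "sample_id"))
    expect_equal(back[[cn]], tab1[[cn]], tolerance = 1e-12)
})

test_that("synthetic bundle tables reload with depths in the stated range", {
  b <- generate_dataset(generator_params(n_taxa = 80, n_modules = 2,
                                         module_size_range = c(10, 15),
                                         seed = 7))
  d <- file.path(tempdir(), "bundle_io")
  write_bundle(b, d)
  back <- read_otu_table(file.path(d, "otu.tsv"))
  expect_equal(back$counts, b$otu$counts)
  expect_true(all(rowSums(back$counts) >= 110000 &
                  rowSums(back$counts) <= 128000))
  met <- read_metal_table(file.path(d, "metals.tsv"))
  expect_equal(met$total_Cd, b$metals$total_Cd, tolerance = 1e-12)
})
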