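test_that("detect_format reads the Format tag cell", {
  expect_identical(detect_format(minimal_csv()), "generic_qhts")
  f <- write_raw_csv(c("Format,NCATS_qHTS", "x,y"))
  expect_identical(detect_format(f), "ncats_qhts")
  f2 <- write_raw_csv(c("Fit_Output,Comp_ID", "1,a"))
  expect_error(detect_format(f2), "no Format tag")
})

test_that("the ncats dialect is recognized and rejected with guidance", {
  f <- write_raw_csv(c("Format,ncats_qhts", "whatever"))
  expect_error(read_generic_qhts(f), "ncats_qhts.*generic")
})

test_that("a minimal generic file parses with order, params and grid intact", {
  ds <- read_generic_qhts(minimal_csv())
  expect_identical(ds$format_tag, "generic_qhts")
  expect_equal(ds$log_conc_m, c(-8, -7, -6))
  expect_length(ds$records, 2L)
  expect_identical(vapply(ds$records, `[[`, "", "comp_id"),
                   c("cmpd-1", "cmpd-2"))
  expect_equal(ds$records[[1]]$params$log_ac50_m, -7)
  # points-only row: loadable with no parameters at all
  expect_null(ds$records[[2]]$params)
  expect_identical(ds$records[[2]]$fit_output, 0L)
})

test_that("a file without parameter columns is loadable for points-only rows", {
  f <- write_raw_csv(c(
    "Format,generic_qhts,Log_Conc_M,-8,-7,-6",
    "Fit_Output,Comp_ID,Readout,Data0,Data1,Data2",
    "0,solo,FLuc,1,2,3"))
  ds <- read_generic_qhts(f)
  expect_length(ds$records, 1L)
  expect_null(ds$records[[1]]$params)
})

test_that("an 11-point titration yields an 11-point grid", {
  f <- tempfile(fileext = ".csv")
  generate_example_file(f, generator_spec(n_compounds = 3, seed = 5))
  ds <- read_generic_qhts(f)
  expect_length(ds$log_conc_m, 11L)
  grep_hdr <- readLines(f, n = 2)[2]
  expect_match(grep_hdr, "Data10")
  expect_false(grepl("Data11", grep_hdr))
})

test_that("malformed data blocks are rejected with the offending column named", {
  non_contig <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,-7,,-6",
    "Fit_Output,Comp_ID,Readout,,Data0,Data1,gap,Data2",
    "0,a,FLuc,,1,2,,3"))
  expect_error(read_generic_qhts(non_contig), "contiguous")
  skipped <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,-7,-6",
    "Fit_Output,Comp_ID,Readout,,Data0,Data1,Data3",
    "0,a,FLuc,,1,2,3"))
  expect_error(read_generic_qhts(skipped), "Data3")
  not_zero <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,-7",
    "Fit_Output,Comp_ID,Readout,,Data1,Data2",
    "0,a,FLuc,,1,2"))
  expect_error(read_generic_qhts(not_zero), "Data0")
  bad_conc <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,oops,-6",
    "Fit_Output,Comp_ID,Readout,,Data0,Data1,Data2",
    "0,a,FLuc,,1,2,3"))
  expect_error(read_generic_qhts(bad_conc), "concentration.*Data1")
})

test_that("a fitted row with missing parameters fails with a row locator", {
  f <- write_raw_csv(c(
    "Format,generic_qhts,,,,,Log_Conc_M,-8,-7,-6",
    "Fit_Output,Comp_ID,Readout,Log_AC50_M,S_0,S_Inf,Hill_Slope,Data0,Data1,Data2",
    "1,cmpd-1,FLuc,-7,0,,1,5,50,95"))
  expect_error(read_generic_qhts(f), "row 3.*S_Inf")
})

test_that("empty, NA and NaN cells all mean a missing response", {
  f <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,-7,-6,-5",
    "Fit_Output,Comp_ID,Readout,,Data0,Data1,Data2,Data3",
    "0,a,FLuc,,1,,NA,nan"))
  ds <- read_generic_qhts(f)
  expect_equal(ds$records[[1]]$responses, c(1, NA, NA, NA))
  f2 <- write_raw_csv(c(
    "Format,generic_qhts,,Log_Conc_M,-8,-7,-6,-5",
    "Fit_Output,Comp_ID,Readout,,Data0,Data1,Data2,Data3",
    "0,a,FLuc,,1,2,junk,4"))
  expect_error(read_generic_qhts(f2), "junk")
})

test_that("header matching is case-insensitive and whitespace-trimmed", {
  f <- write_raw_csv(c(
    "format,Generic_QHTS,,,,, log_conc_m ,-8,-7,-6",
    "FIT_OUTPUT, comp_id ,READOUT,log_ac50_m,s_0,s_inf,HILL_SLOPE,data0,Data1,DATA2",
    "1,x,FLuc,-7,0,100,1,5,50,95"))
  ds <- read_generic_qhts(f)
  expect_length(ds$records, 1L)
  expect_equal(ds$records[[1]]$params$s_inf, 100)
  # canonical names come back out
  out <- tempfile(fileext = ".csv")
  write_generic_qhts(ds, out)
  expect_match(readLines(out, n = 2)[2], "Fit_Output,Comp_ID,Readout")
})

test_that("annotation columns are preserved by name, order and value", {
  f <- write_raw_csv(c(
    "Format,generic_qhts,,,,,,,Log_Conc_M,-8,-7,-6",
    "Fit_Output,Comp_ID,Readout,Sample Name,SMILES,Log_AC50_M,S_0,S_Inf,Hill_Slope,Data0,Data1,Data2",
    '1,c1,FLuc,"name, with comma",CCO,-7,0,100,1,5,50,95'))
  ds <- read_generic_qhts(f)
  expect_identical(names(ds$records[[1]]$annotations), c("Sample Name", "SMILES"))
  expect_identical(unname(ds$records[[1]]$annotations[1]), "name, with comma")
  # survives a round trip, including the quoted comma
  out <- tempfile(fileext = ".csv")
  write_generic_qhts(ds, out)
  expect_true(dataset_equal(read_generic_qhts(out), ds))
})

test_that("write/read round-trips are the identity for csv and xlsx", {
  out <- generate_dataset(generator_spec(n_compounds = 40, seed = 17))
  ds <- out$dataset
  for (ext in c(".csv", ".xlsx")) {
    f1 <- tempfile(fileext = ext)
    write_generic_qhts(ds, f1)
    d1 <- read_generic_qhts(f1)
    expect_true(dataset_equal(d1, ds), info = ext)
    # double round-trip: the re-read of a rewrite is also identical
    f2 <- tempfile(fileext = ext)
    write_generic_qhts(d1, f2)
    expect_true(dataset_equal(read_generic_qhts(f2), ds), info = ext)
  }
  # the two encodings parse to equal datasets
  fc <- tempfile(fileext = ".csv"); fx <- tempfile(fileext = ".xlsx")
  write_generic_qhts(ds, fc); write_generic_qhts(ds, fx)
  expect_true(dataset_equal(read_generic_qhts(fc), read_generic_qhts(fx)))
})

test_that("validation separates errors from warnings", {
  out <- generate_dataset(generator_spec(n_compounds = 25, seed = 2))
  rep <- validate_qhts(out$dataset)
  expect_true(rep$ok)
  expect_identical(nrow(rep$issues), 0L)

  # fitted record with zero Hill slope: error citing the record
  bad <- tiny_dataset()
  bad$records[[1]]$params$hill_slope <- 0
  rep2 <- validate_qhts(bad)
  expect_false(rep2$ok)
  expect_match(rep2$issues$message[rep2$issues$severity == "error"], "Hill_Slope")
  expect_match(rep2$issues$locator[rep2$issues$severity == "error"], "record 1")
  expect_error(write_generic_qhts(bad, tempfile(fileext = ".csv")), "refusing")

  # shuffled, non-monotonic grid: legal but flagged
  shuf <- tiny_dataset()
  shuf$log_conc_m <- shuf$log_conc_m[c(3, 1, 5, 2, 4)]
  rep3 <- validate_qhts(shuf)
  expect_true(rep3$ok)
  expect_match(rep3$issues$message, "monotonic", all = FALSE)

  # wild response scale: warning only
  wild <- tiny_dataset()
  wild$records[[3]]$responses[1] <- 1e4
  rep4 <- validate_qhts(wild)
  expect_true(rep4$ok)
  expect_match(rep4$issues$message, "-200", all = FALSE)

  # duplicate (comp_id, readout): warning
  dup <- tiny_dataset()
  dup$records[[2]]$readout <- "FLuc"
  rep5 <- validate_qhts(dup)
  expect_true(rep5$ok)
  expect_match(rep5$issues$message, "duplicate", all = FALSE)
})

test_that("the reader never reorders rows", {
  out <- generate_dataset(generator_spec(n_compounds = 30, seed = 8))
  f <- tempfile(fileext = ".csv")
  write_generic_qhts(out$dataset, f)
  back <- read_generic_qhts(f)
  expect_identical(vapply(back$records, `[[`, "", "comp_id"),
                   vapply(out$dataset$records, `[[`, "", "comp_id"))
  expect_identical(vapply(back$records, `[[`, "", "readout"),
                   vapply(out$dataset$records, `[[`, "", "readout"))
})
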