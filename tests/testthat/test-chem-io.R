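example_sdf <- system.file("extdata", "example.sdf", package = "admetscreen")

test_that("SDF reading yields one record per molecule block with tags kept", {
  mols <- read_structures(example_sdf, "sdf")
  expect_length(mols, 2)
  expect_equal(purrr::map_chr(mols, "id"), c("methane", "water"))
  expect_equal(n_atoms(mols[[1]]), 5)
  expect_equal(mols[[1]]$properties$logS_wat, "-0.5")
  expect_equal(nrow(mols[[2]]$bonds), 2)
})

test_that("SMILES lines become records with the right heavy-atom counts", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
  mols <- read_structures(smi, "smiles")
  expect_length(mols, 2)
  expect_equal(n_atoms(mols[[1]], heavy = TRUE), 3)
  expect_equal(n_atoms(mols[[2]], heavy = TRUE), 6)
})

test_that("a corrupt bond block fails naming the offending record", {
  bad <- withr::local_tempfile(fileext = ".sdf")
  blocks <- readLines(example_sdf)
  corrupt <- c(
    "broken", "", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  9  1  0  0  0  0",  # bond to nonexistent atom 9
    "M  END", "$$$$")
  writeLines(c(blocks, corrupt), bad)
  expect_error(read_structures(bad, "sdf"), "record 3")
})

test_that("an empty structure file warns and returns an empty list", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_warning(mols <- read_structures(empty, "sdf"), "empty")
  expect_length(mols, 0)
})

test_that("descriptor tables resolve aliases and keep raw unresolved names", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule,mol.MW,QPlogPo/w,mystery",
               "c1,410.5,3.2,7",
               "c2,222.1,1.1,8"), csv)
  expect_warning(prof <- read_descriptor_table(csv, "qikprop_export"),
                 "mystery")
  expect_named(prof, c("id", "MW", "logP", "mystery"))
  expect_equal(prof$MW, c(410.5, 222.1))
  expect_equal(unname(provenance(prof)[c("MW", "logP")]),
               c("imported", "imported"))
})

test_that("missing cells stay absent and are never imputed", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,logS_wat", paste0("c", 1:5, ",",
                                     c("-3.1", "", "-4.2", "-5.0", "-1.9"))),
             csv)
  prof <- read_descriptor_table(csv)
  expect_equal(nrow(prof), 5)
  expect_equal(sum(!is.na(prof$logS_wat)), 4)
})

test_that("duplicate ids and non-numeric numeric cells are errors", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,MW", "cmp1,100", "cmp1,200"), dup)
  expect_error(read_descriptor_table(dup), "cmp1")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,MW", "c1,abc"), bad)
  expect_error(read_descriptor_table(bad), "MW.*row 1|row 1")
})

test_that("write/read round-trips preserve values in every format", {
  cfg <- synthetic_config(n = 10, seed = 3)
  prof <- generate_profiles(cfg)
  for (fmt in c("csv", "sdf_tags")) {
    f <- withr::local_tempfile(fileext = if (fmt == "csv") ".csv" else ".sdf")
    write_profiles(prof, f, fmt)
    back <- read_descriptor_table(
      f, dialect = if (fmt == "csv") "generic_csv" else "sdf_tags")
    back <- back[match(prof$id, back$id), names(prof)]
    for (d in setdiff(names(prof), "id")) {
      expect_equal(back[[d]], prof[[d]], tolerance = 1e-6,
                   info = paste(fmt, d))
    }
  }
})

test_that("writing rejects empty input and warns on unregistered keys", {
  expect_error(write_profiles(tibble::tibble(), tempfile()), "non-empty")
  f <- withr::local_tempfile(fileext = ".csv")
  expect_warning(
    write_profiles(tibble::tibble(id = "a", MW = 100, oddball = 1), f),
    "oddball")
  expect_warning(back <- read_descriptor_table(f), "oddball")
  expect_equal(back$oddball, 1)
})

test_that("alias resolution is idempotent on canonical names", {
  canon <- descriptor_registry()$canonical
  expect_equal(resolve_descriptor_names(canon), canon)
  expect_equal(resolve_descriptor_names(c("#stars", "QPlogS")),
               c("stars", "logS_wat"))
  expect_true(is.na(resolve_descriptor_names("not_a_descriptor")))
})
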