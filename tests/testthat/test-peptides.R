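test_that("parsing canonicalizes, validates, and is idempotent", {
  p <- parse_peptide(" rkkrrqrrr ", id = "tat9", label = "CPP")
  expect_s3_class(p, "peptide")
  expect_identical(p$sequence, "RKKRRQRRR")
  expect_identical(nchar(p$sequence), 9L)
  # idempotence
  expect_identical(parse_peptide(p$sequence, "x")$sequence, p$sequence)
})

test_that("illegal inputs are rejected with informative errors", {
  expect_error(parse_peptide("", "x"), "EmptySequence")
  expect_error(parse_peptide("   ", "x"), "EmptySequence")
  expect_error(parse_peptide("RKKB1", "x"), "InvalidResidue.*'B'.*position 4")
  for (ch in c("X", "Z", "U", "O", "J", "7", "-")) {
    expect_error(parse_peptide(paste0("AC", ch), "x"), "InvalidResidue")
  }
})

test_that("bundled fixtures have the documented counts, labels and alphabet", {
  cpp <- load_bundled("cpp111")
  non <- load_bundled("noncpp34")
  val <- load_bundled("validation13")
  expect_length(cpp, 111)
  expect_length(non, 34)
  expect_length(val, 13)
  expect_true(all(collection_labels(cpp) == "CPP"))
  expect_true(all(collection_labels(non) == "NON_CPP"))
  # every fixture sequence already passed alphabet validation at load;
  # assert explicitly on the raw strings
  all_seq <- c(collection_sequences(cpp), collection_sequences(non),
               collection_sequences(val))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", all_seq)))
  expect_error(load_bundled("nope"), "UnknownDataset")
})

test_that("validation fixtures keep printed lengths after amidation stripping", {
  val <- load_bundled("validation13")
  seqs <- collection_sequences(val)
  ids <- collection_ids(val)
  expect_identical(nchar(seqs[ids == "TP13"]), 20L)
  expect_identical(unname(seqs[ids == "TP13"]), "LNSAGYLLGKALAALAKKIL")
  expect_identical(nchar(seqs[ids == "HIV-TAT"]), 11L)
  expect_identical(nchar(seqs[ids == "Pep-1"]), 21L)
  # amidation is metadata only
  expect_true(all(vapply(val$peptides, function(p) isTRUE(attr(p, "amidated")),
                         logical(1))))
  # role-derived labels
  labs <- collection_labels(val)
  expect_identical(sum(labs == "CPP"), 3L)      # positive controls
  expect_identical(sum(labs == "NON_CPP"), 4L)  # negative controls + TP13
})

test_that("FASTA round trip preserves ids and sequences", {
  cpp <- load_bundled("cpp111")
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(cpp, tmp)
  back <- read_fasta(tmp, label = "CPP")
  expect_length(back, 111)
  expect_identical(collection_ids(back), collection_ids(cpp))
  expect_identical(unname(collection_sequences(back)),
                   unname(collection_sequences(cpp)))
})

test_that("FASTA reader rejects junk and non-canonical residues", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEFXK"), tmp)
  expect_error(read_fasta(tmp), "InvalidResidue")
  expect_error(read_fasta("no/such/file.fasta"), "not found")
})

test_that("collections enforce id uniqueness but subsetting can resample", {
  p1 <- parse_peptide("ACDE", "a")
  expect_error(peptide_collection(list(p1, p1)), "duplicate")
  coll <- peptide_collection(list(p1, parse_peptide("KKKK", "b")))
  dup <- coll[c(1, 1, 2)]
  expect_length(dup, 3)
  expect_identical(collection_ids(dup), c("a", "a_dup1", "b"))
  expect_identical(unname(collection_sequences(dup)[1:2]), c("ACDE", "ACDE"))
})

test_that("synthetic stand-in pool is deterministic and valid", {
  pool <- synthetic_peptide_pool(n = 50)
  pool2 <- synthetic_peptide_pool(n = 50)
  expect_identical(collection_sequences(pool), collection_sequences(pool2))
  lens <- nchar(collection_sequences(pool))
  expect_true(all(lens >= 12 & lens <= 26))
})
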