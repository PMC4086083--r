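test_that("fingerprint dimensions match their space definitions", {
  for (sp in FP_SPACES) {
    f <- fingerprint("CNC[C@H](O)c1ccc(O)c(O)c1", sp)
    expect_length(f$values, FP_LENGTHS[[sp]])
    expect_true(all(f$values >= 0L))
    if (sp %in% c("sfp", "ecfp4")) expect_true(all(f$values %in% 0:1))
    expect_identical(f$total_sum, sum(f$values))
  }
})

test_that("encoder defaults are path length 7 and bond diameter 4", {
  expect_identical(eval(formals(fingerprint)$max_path), 7L)
  expect_identical(eval(formals(fingerprint)$diameter), 4L)
  expect_identical(eval(formals(fingerprint_matrix)$max_path), 7L)
  expect_identical(eval(formals(fingerprint_matrix)$diameter), 4L)
})

test_that("MQN counts match hand counts on the molecular graph", {
  nm <- fpbrowse:::MQN_NAMES
  methane <- fingerprint("C", "mqn")$values
  names(methane) <- nm
  expect_equal(methane[["c"]], 1L)
  expect_equal(methane[["hac"]], 1L)
  expect_true(all(methane[c("r3", "r4", "r5", "r6", "r7", "r8", "r9",
                            "rg10")] == 0L))

  benzene <- fingerprint("c1ccccc1", "mqn")$values
  names(benzene) <- nm
  expect_equal(benzene[["r6"]], 1L)
  expect_equal(benzene[["csb"]] + benzene[["cdb"]], 6L)  # kekulized ring
  expect_equal(benzene[["cdv"]], 6L)

  # fused bicyclic: naphthalene shares one bond and two atoms
  naph <- fingerprint("c1ccc2ccccc2c1", "mqn")$values
  names(naph) <- nm
  expect_equal(naph[["r6"]], 2L)
  expect_equal(naph[["afr"]], 2L)
  expect_equal(naph[["bfr"]], 1L)

  # ethanol polarity block: O has 2 lone pairs and 1 hydrogen
  eth <- fingerprint("CCO", "mqn")$values
  names(eth) <- nm
  expect_equal(eth[["hbam"]], 2L)
  expect_equal(eth[["hba"]], 1L)
  expect_equal(eth[["hbdm"]], 1L)
  expect_equal(eth[["hbd"]], 1L)
  expect_equal(eth[["rbc"]], 0L)  # C-O bond ends on a terminal atom
})

test_that("MQN heavy-atom count is consistent with per-element counts", {
  lib <- small_library()
  m <- fingerprint_matrix(lib, "mqn")$values
  colnames(m) <- fpbrowse:::MQN_NAMES
  parts <- rowSums(m[, c("c", "f", "cl", "br", "i", "s", "p",
                         "an", "cn", "ao", "co")])
  expect_equal(unname(parts), unname(m[, "hac"]))
})

test_that("SMIfp equals a literal character-count oracle", {
  syms <- fpbrowse:::SMIFP_SYMBOLS
  for (smi in c("CCO", "Clc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
                "C[NH+](C)C", "BrCC/C=C/CBr")) {
    can <- canonical_smiles(smi)
    v <- fingerprint(smi, "smifp")$values
    names(v) <- syms
    for (s in syms) {
      expect_equal(v[[s]], count_symbol(can, s),
                   label = sprintf("count of %s in %s", s, can))
    }
  }
  v <- fingerprint("Clc1ccccc1", "smifp")$values
  names(v) <- syms
  expect_equal(v[["Cl"]], 1L)
  expect_equal(v[["c"]], 6L)
  expect_equal(v[["1"]], 2L)  # ring-closure digit counted twice
})

test_that("single-path and single-environment molecules set one bit", {
  expect_equal(fingerprint("C", "sfp")$total_sum, 1L)
  expect_equal(fingerprint("C", "ecfp4")$total_sum, 1L)
  # two atoms: paths C, O, C-O -> 3 bits unless hash collision (none here)
  expect_equal(fingerprint("CO", "sfp")$total_sum, 3L)
})

test_that("encoders are pure functions of the canonical structure", {
  variants <- list(
    c("CCO", "OCC", "C(O)C"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("Cc1ccccc1", "c1ccccc1C", "c1ccc(C)cc1"),
    c("CNC[C@H](O)c1ccc(O)c(O)c1", "Oc1ccc(cc1O)[C@@H](O)CNC"))
  for (sp in FP_SPACES) {
    for (vs in variants) {
      fps <- lapply(vs, function(s) fingerprint(s, sp)$values)
      for (i in seq_along(fps)[-1]) {
        expect_identical(fps[[i]], fps[[1]],
                         label = sprintf("%s of %s", sp, vs[i]))
      }
    }
  }
})

test_that("stored total sums always match recomputation from values", {
  lib <- small_library()[1:60, ]
  for (sp in FP_SPACES) {
    fps <- fingerprint_matrix(lib, sp)
    expect_identical(fps$total_sum, as.integer(rowSums(fps$values)))
  }
})

test_that("fingerprint dump TSV round-trips binary and count spaces", {
  lib <- small_library()[1:10, ]
  for (sp in c("ecfp4", "mqn")) {
    fps <- fingerprint_matrix(lib, sp)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_fingerprints(lib$id, fps, path)
    back <- read_fingerprints(path)
    expect_identical(back$ids, lib$id)
    expect_identical(unname(back$fps$values), unname(fps$values))
    expect_identical(back$fps$total_sum, fps$total_sum)
  }
})
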