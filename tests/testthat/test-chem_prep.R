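test_that("SMILES parsing makes hydrogens explicit with correct connectivity", {
  methane <- methane_record()
  expect_length(methane$elements, 5)
  expect_equal(nrow(methane$bonds), 4)
  expect_true(all(methane$elements[c(2, 3, 4, 5)] == "H"))

  ethane <- ethane_record()
  expect_length(ethane$elements, 8)
  expect_equal(nrow(ethane$bonds), 7)
  is_cc <- ethane$elements[ethane$bonds$a] == "C" &
    ethane$elements[ethane$bonds$b] == "C"
  expect_equal(sum(is_cc), 1)
  expect_equal(sum(!is_cc), 6)

  expect_error(parse_molecule("not-a-smiles", "badmol"), "badmol")
})

test_that("benzene carbons are aromatic, agreeing with an independent toolkit", {
  benzene <- parse_molecule("c1ccccc1", "benzene")
  expect_true(all(benzene$aromatic[benzene$elements == "C"]))
  expect_false(any(benzene$aromatic[benzene$elements == "H"]))

  # independent oracle: OpenBabel's mol2 atom typing
  mol2 <- ChemmineOB::convertFormat("SMI", "MOL2", "c1ccccc1 benzene",
                                    options = data.frame(names = "h", args = ""))
  lines <- strsplit(mol2, "\n")[[1]]
  ai <- grep("@<TRIPOS>ATOM", lines)
  bi <- grep("@<TRIPOS>BOND", lines)
  types <- vapply(strsplit(trimws(lines[(ai + 1):(bi - 1)]), "[[:space:]]+"),
                  `[[`, "", 6)
  expect_equal(sum(types == "C.ar"), sum(benzene$aromatic))
})

test_that("element/size filter follows the H,C,N,O and seven-heavy-atom rules", {
  expect_true(passes_filter(parse_molecule("CCCCCCC", "heptane")))
  expect_false(passes_filter(parse_molecule("CCCCCCCC", "octane")))
  expect_false(passes_filter(parse_molecule("CCl", "chloromethane")))
  expect_true(passes_filter(parse_molecule("CC(N)O", "aminoethanol")))
  # the heavy-atom criterion is monotone: every sub-chain of heptane passes
  for (n in 1:6) {
    expect_true(passes_filter(parse_molecule(strrep("C", n), paste0("chain", n))))
  }
})

test_that("neutral closed-shell validity check rejects ions unless overridden", {
  expect_error(parse_molecule("[NH4+]", "ammonium"), "charge")
  rec <- parse_molecule("[NH4+]", "ammonium", require_neutral = FALSE)
  expect_equal(sum(rec$formal_charges), 1L)
  expect_error(parse_molecule("[CH3]", "methyl-radical"), "radical")
})

test_that("hydrogen explicitness: carbon bond counts equal declared valence", {
  for (smi in c("C", "CC", "CCC", "CC(N)O", "CCC(C)(C)C")) {
    rec <- parse_molecule(smi, smi)
    for (i in which(rec$elements == "C")) {
      deg <- sum(rec$bonds$a == i | rec$bonds$b == i)
      expect_equal(deg, rec$valences[i], info = paste(smi, "atom", i))
    }
  }
})

test_that("embedding is deterministic per seed and geometrically sane", {
  g <- ethane_geom()
  # cache-busted re-embedding must be bit-identical
  rm(list = ls(envir = bondbreakr:::.bridge_cache),
     envir = bondbreakr:::.bridge_cache)
  g2 <- embed_geometry(ethane_record(), seed = 0)
  expect_identical(g$coords, g2$coords)

  g3 <- embed_geometry(ethane_record(), seed = 7)
  expect_false(identical(g$coords, g3$coords))

  d_cc <- atom_distance(g, 1, 2)
  expect_gt(d_cc, 1.4)
  expect_lt(d_cc, 1.7)

  gm <- embed_geometry(methane_record(), seed = 0)
  ch <- vapply(2:5, function(i) atom_distance(gm, 1, i), 1.0)
  expect_lt(max(ch) - min(ch), 0.05)

  # all bonded distances physical
  rec <- ethane_record()
  d <- vapply(seq_len(nrow(rec$bonds)), function(i) {
    atom_distance(g, rec$bonds$a[i], rec$bonds$b[i])
  }, 1.0)
  expect_true(all(d > 0.7 & d < 2.0))
})

test_that("molecule tables round through CSV input", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(identifier = c("methane", "ethane"),
                       smiles = c("C", "CC")), f, row.names = FALSE)
  recs <- read_molecule_table(f)
  expect_named(recs, c("methane", "ethane"))
  expect_equal(nrow(recs$ethane$bonds), 7)
})
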