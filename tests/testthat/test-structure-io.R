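# Coordinate I/O: altloc/occupancy/deuterium preservation, round-trips,
# ensembles and the selection language.

minimal_pdb <- function(path) {
  writeLines(c(
    "CRYST1   79.700   96.100  105.500  90.00  90.00  90.00 I 2 2 2",
    "ATOM      1  OG1 THR A  57      12.345   7.500  -4.500  1.00  8.00           O",
    "END"), path)
  path
}

test_that("a minimal one-atom file parses with full defaults", {
  f <- minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  m <- read_structure(f)
  expect_equal(n_atoms(m), 1L)
  expect_equal(n_frames(m), 1L)
  expect_equal(m$atoms$occupancy, 1)
  expect_equal(m$atoms$element, "O")
  expect_equal(m$spacegroup, "I 2 2 2")
  expect_equal(coords(m)[1, ], c(12.345, 7.5, -4.5))
})

test_that("write/read round-trip preserves coordinates, altlocs, occupancies and deuterium", {
  toy <- build_toy_active_site()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$model, f)
  m2 <- read_structure(f)
  expect_equal(n_atoms(m2), n_atoms(toy$model))
  expect_equal(m2$atoms$name, toy$model$atoms$name)
  expect_equal(m2$atoms$altloc, toy$model$atoms$altloc)
  expect_equal(m2$atoms$occupancy, toy$model$atoms$occupancy, tolerance = 1e-9)
  expect_equal(m2$atoms$element, toy$model$atoms$element)   # "D" survives
  expect_lt(max(abs(coords(m2) - coords(toy$model))), 0.001 + 1e-12)
  # second write is byte-identical (fixed-column format is canonical)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  expect_identical(readLines(f), readLines(f2))
  # altloc occupancies as modelled: 0.75 / 0.25 conformers both present
  a <- m2$atoms[m2$atoms$resname == "ASN" & m2$atoms$altloc != "", ]
  expect_setequal(unique(a$occupancy), c(0.75, 0.25))
})

test_that("malformed and duplicate records are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad-x    1.000   1.000  1.00 10.00           C",
               "END"), f)
  expect_error(read_structure(f), "line 1")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       1.000   1.000   1.000  1.00 10.00           C",
               "ATOM      2  CA  ALA A   1       2.000   1.000   1.000  1.00 10.00           C",
               "END"), f2)
  expect_error(read_structure(f2), "duplicate atom key")
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")), "no such file")
})

test_that("a minimal mmCIF atom_site loop parses with occupancy and deuterium", {
  f <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_test", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  writeLines(c(hdr,
               "ATOM 1 O OG1 . THR A 1 57 ? 12.345 7.500 -4.500 1.00 8.00 ? 57 THR A OG1 1",
               "ATOM 2 D DG1 . THR A 1 57 ? 12.900 8.100 -4.000 0.78 9.00 ? 57 THR A DG1 1"), f)
  m <- read_structure(f, dialect = "mmcif")
  expect_equal(n_atoms(m), 2L)
  expect_equal(m$atoms$element, c("O", "D"))
  expect_equal(m$atoms$occupancy, c(1, 0.78))
  expect_equal(coords(m)[1, ], c(12.345, 7.5, -4.5))
})

test_that("empty models cannot be written", {
  toy <- build_toy_active_site()$model
  empty <- toy
  empty$xyz <- toy$xyz[integer(0), , , drop = FALSE]
  empty$atoms <- toy$atoms[integer(0), ]
  expect_error(write_structure(empty, withr::local_tempfile()), "empty model")
})

test_that("multi-model files yield one frame per model", {
  toy <- build_toy_active_site()$model
  ens <- structure_model(toy$atoms,
                         array(rep(toy$xyz[, , 1], 3) + rep(c(0, 0.5, 1), each = length(toy$xyz[, , 1])),
                               dim = c(n_atoms(toy), 3, 3)),
                         source = "triple")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, f)
  m <- read_structure(f)
  expect_equal(n_frames(m), 3L)
  expect_lt(max(abs(coords(m, 2) - coords(ens, 2))), 0.001 + 1e-12)
})

test_that("the selection language is deterministic and altloc-aware", {
  toy <- build_toy_active_site()$model
  lig <- select_atoms(toy, "chain A and resname AZA")
  expect_true(all(toy$atoms$resname[lig] == "AZA"))
  expect_equal(length(lig), sum(toy$atoms$resname == "AZA"))
  expect_identical(lig, select_atoms(toy, "chain A and resname AZA"))
  # blank-altloc atoms are shared by every conformer: an altloc filter keeps them
  asn <- select_atoms(toy, "resno 254")
  asn_a <- select_atoms(toy, "resno 254 and altloc A")
  expect_true(all(toy$atoms$altloc[asn_a] %in% c("", "A")))
  expect_true(any(toy$atoms$altloc[asn_a] == ""))      # shared backbone retained
  expect_lt(length(asn_a), length(asn))
  expect_equal(length(select_atoms(toy, "element D and resname THR")), 1L)
  expect_warning(select_atoms(toy, "resname XYZ"), "matches no atoms")
  expect_error(select_atoms(toy, "resname XYZ", on_missing = "error"))
  expect_error(select_atoms(toy, "frobnicate Q"), "unknown selection keyword")
})

test_that("altloc expansion duplicates shared atoms into every conformer", {
  toy <- build_toy_active_site()$model
  asn <- select_atoms(toy, "resno 254 and chain A")
  ex <- altloc_expand(toy, asn)
  expect_setequal(names(ex), c("A", "B"))
  shared <- asn[toy$atoms$altloc[asn] == ""]
  expect_true(all(shared %in% ex$A) && all(shared %in% ex$B))
  expect_false(any(toy$atoms$altloc[ex$A] == "B"))
})

test_that("frame tables round-trip and inconsistent frames are named", {
  ens <- generate_ensemble(ensemble_spec(n = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_frame_table(ens$model, f, digits = 6)
  m <- read_ensemble(f)
  expect_equal(n_frames(m), 5L)
  expect_equal(m$atoms$name, ens$model$atoms$name)
  expect_lt(max(abs(m$xyz - ens$model$xyz)), 1e-6 + 1e-12)
  # drop one atom row from frame 3 -> error naming the frame and the atom
  tab <- utils::read.csv(f)
  bad <- withr::local_tempfile(fileext = ".csv")
  drop <- which(tab$frame == 3 & tab$name == "OG1")[1]
  utils::write.csv(tab[-drop, ], bad, row.names = FALSE, quote = FALSE)
  expect_error(read_ensemble(bad), "frame 3.*OG1")
})

test_that("single-model PDB reads as a one-frame ensemble", {
  toy <- build_toy_active_site()$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, f)
  m <- read_ensemble(f)
  expect_equal(n_frames(m), 1L)
})

test_that("residue content is summarized by class", {
  toy <- build_toy_active_site()$model
  rs <- residue_summary(toy)
  expect_equal(rs$waters, 2L)
  expect_equal(rs$waters_with_d, 1L)       # W1 has D1/D2, W2 is O-only
  expect_equal(rs$waters_o_only, 1L)
  expect_equal(unname(rs$ligands["AZA"]), 1L)
})
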