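write_lines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("FASTA MSAs round-trip and parse species from UniProt headers", {
  path <- write_lines(c(
    ">sp|P07550|ADRB2_HUMAN", "MKLV-A",
    ">tr|Q000|ADRB2_MOUSE", "MKIVQA",
    ">tr|Q001|ADRB2_RAT", "MRIVQA"
  ), ".fasta")
  fam <- read_fasta_msa(path)
  expect_s3_class(fam, "aligned_family")
  expect_equal(nrow(fam$sequences), 3)
  expect_equal(fam$sequences$species, c("HUMAN", "MOUSE", "RAT"))
  expect_equal(family_target(fam), "sp|P07550|ADRB2_HUMAN")

  out <- tempfile(fileext = ".fasta")
  write_fasta_msa(fam, out)
  fam2 <- read_fasta_msa(out)
  expect_equal(fam2$sequences$residues, fam$sequences$residues)
  expect_equal(fam2$sequences$seq_id, fam$sequences$seq_id)
})

test_that("ragged and empty FASTA inputs are hard errors", {
  ragged <- write_lines(c(">a_HUMAN", "MKLVPQWERT", ">b_MOUSE", "MKLVPQWER"),
                        ".fasta")
  expect_error(read_fasta_msa(ragged), "ragged")
  empty <- write_lines(character(0), ".fasta")
  expect_error(read_fasta_msa(empty), "empty|read")
  expect_error(read_fasta_msa(tempfile()), "not found")
})

test_that("Newick trees load with species metadata, polytomies tolerated", {
  p1 <- write_lines("((a_HUMAN,b_MOUSE),(c_RAT,d_FROG));", ".nwk")
  gt <- read_newick(p1)
  expect_equal(length(gt$phy$tip.label), 4)
  expect_true(gt$leaves$is_human[gt$leaves$seq_id == "a_HUMAN"])

  p2 <- write_lines("((a_HUMAN,b_MOUSE,c_RAT),d_FROG);", ".nwk")
  gt2 <- read_newick(p2)
  expect_equal(gt2$phy$Nnode, 2)  # one polytomy retained at load

  p3 <- write_lines("((a_HUMAN,b_MOUSE);", ".nwk")
  expect_error(read_newick(p3))

  p4 <- write_lines("((aHUMAN,b_MOUSE),(c_RAT,d_FROG));", ".nwk")
  expect_error(read_newick(p4), "aHUMAN")
})

pdb_line <- function(serial, name, resno, x, y, z, element,
                     altloc = " ", occ = 1.00) {
  sprintf("ATOM  %5d %-4s%sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resno, x, y, z, occ, 0.0, element)
}

test_that("PDB reading drops hydrogens and annotates generic numbers", {
  lines <- c(
    pdb_line(1, " N  ", 1, 0, 0, 0, "N"),
    pdb_line(2, " CA ", 1, 1.5, 0, 0, "C"),
    pdb_line(3, " H  ", 1, 2.0, 1, 0, "H"),
    pdb_line(4, " CA ", 2, 5, 0, 0, "C"),
    pdb_line(5, " CA ", 3, 9, 0, 0, "C"),
    "END"
  )
  path <- write_lines(lines, ".pdb")
  map <- generic_number_map(
    tibble::tibble(residue_index = 1L, generic_number = "3x50"))
  s <- read_structure(path, generic_map = map, state = "active")
  expect_equal(nrow(s), 4)           # H excluded
  expect_false("H" %in% s$element)
  expect_equal(sum(!is.na(s$generic_number)), 2)  # N + CA of residue 1
  expect_setequal(unique(s$generic_number[!is.na(s$generic_number)]), "3x50")
})

test_that("altlocs keep the highest occupancy and duplicate serials warn", {
  lines <- c(
    pdb_line(1, " CA ", 1, 0, 0, 0, "C", altloc = "A", occ = 0.4),
    pdb_line(2, " CA ", 1, 3, 0, 0, "C", altloc = "B", occ = 0.6),
    pdb_line(3, " CA ", 2, 6, 0, 0, "C"),
    "END"
  )
  s <- read_structure(write_lines(lines, ".pdb"))
  r1 <- s[s$residue_index == 1, ]
  expect_equal(nrow(r1), 1)
  expect_equal(r1$x, 3)  # hand parse: altloc B has occupancy 0.6

  dup <- c(
    pdb_line(7, " CA ", 1, 0, 0, 0, "C"),
    pdb_line(7, " CB ", 1, 1, 0, 0, "C"),
    pdb_line(8, " CA ", 2, 5, 0, 0, "C"),
    "END"
  )
  expect_warning(s2 <- read_structure(write_lines(dup, ".pdb")),
                 "duplicate atom serial")
  expect_equal(nrow(s2), 2)
})

test_that("structures without CA atoms are rejected as non-protein", {
  lines <- c(pdb_line(1, " O  ", 1, 0, 0, 0, "O"), "END")
  expect_error(read_structure(write_lines(lines, ".pdb")),
               "not a protein structure")
})

test_that("heavy-atom count is invariant to atom record order", {
  lines <- c(
    pdb_line(1, " N  ", 1, 0, 0, 0, "N"),
    pdb_line(2, " H  ", 1, 1, 0, 0, "H"),
    pdb_line(3, " CA ", 1, 2, 0, 0, "C"),
    pdb_line(4, " CA ", 2, 6, 0, 0, "C"),
    "END"
  )
  s1 <- read_structure(write_lines(lines, ".pdb"))
  s2 <- read_structure(write_lines(lines[c(3, 1, 4, 2, 5)], ".pdb"))
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sort(s1$atom_name), sort(s2$atom_name))
})

test_that("edge tables are deterministic, sorted, header-only when empty", {
  net <- contact_network(tibble::tibble(
    source = c("7x41", "3x50"), target = c("6x48", "7x53"),
    score = c(1.25, -0.5)
  ))
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_edge_table(net, p1)
  write_edge_table(net, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_equal(length(lines), 3)  # header + 2 edges
  expect_match(lines[1], "^source_generic\ttarget_generic\tscore$")
  body <- do.call(rbind, strsplit(lines[-1], "\t"))
  expect_true(!is.unsorted(body[, 1]))

  empty <- contact_network(tibble::tibble(source = character(0),
                                          target = character(0),
                                          score = numeric(0)))
  p3 <- tempfile(fileext = ".tsv")
  write_edge_table(empty, p3)
  expect_equal(length(readLines(p3)), 1)
  expect_error(write_edge_table(NULL, tempfile()), "NULL")
})

test_that("coupling tables validate vocabulary and uniqueness", {
  tab <- tibble::tibble(
    receptor = c("ADRB2", "ADRB2", "DRD2"),
    g_protein = c("Gs", "Gs", "Gi1"),
    source = c("datasetA", "datasetB", "datasetA"),
    couples = c(1, 0, 1)
  )
  ct <- coupling_table(tab)
  expect_type(ct$couples, "logical")
  expect_error(coupling_table(dplyr::mutate(tab, g_protein = "Gx")),
               "unknown G protein")
  expect_error(coupling_table(tab[c(1, 1, 2), ]), "exactly once")

  grp <- coupling_groups(ct, "Gs", "union")
  expect_equal(grp$couplers, "ADRB2")
  grp2 <- coupling_groups(ct, "Gs", "intersection")
  expect_equal(grp2$couplers, character(0))
})

test_that("generic-number maps validate format and injectivity", {
  expect_error(generic_number_map(
    tibble::tibble(residue_index = 1, generic_number = "7-41")), "malformed")
  expect_error(generic_number_map(
    tibble::tibble(residue_index = c(1, 2), generic_number = c("7x41", "7x41"))),
    "one-to-one")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("residue_index\tgeneric_number", "315\t7x41"), path)
  expect_equal(read_generic_map(path)$generic_number, "7x41")
})
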