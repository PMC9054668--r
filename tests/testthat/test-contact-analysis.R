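test_that("single ATOM line parses field-exactly; altLoc keeps top occupancy", {
  line <- "ATOM     17  CG2 THR A 218      11.500  -2.250   3.125  1.00 15.00           C"
  rec <- parse_coordinates(line)
  expect_identical(rec$serial, 17L)
  expect_identical(rec$atom_name, "CG2")
  expect_identical(rec$residue_name, "THR")
  expect_identical(rec$chain_id, "A")
  expect_identical(rec$residue_number, 218L)
  expect_equal(c(rec$x, rec$y, rec$z), c(11.5, -2.25, 3.125))
  expect_identical(rec$element, "C")

  alt <- c(
    "ATOM      1  CB ATHR A  10       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CB BTHR A  10       1.000   0.000   0.000  0.40 10.00           C")
  rec2 <- parse_coordinates(alt)
  expect_identical(nrow(rec2), 1L)
  expect_identical(rec2$alt_loc, "A")
  expect_error(parse_coordinates("REMARK nothing"), "argument")
  expect_error(parse_coordinates("ATOM      1  CB  THR A  10      bad"), "parse")
})

test_that("generated helix round-trips through PDB text to 3 decimals", {
  pdb <- synth_helix_pdb(12, c("LEU", "THR", "ALA"), chains = 2, axis_sep = 9)
  atoms <- parse_coordinates(pdb)
  back <- parse_coordinates(write_pdb(atoms))
  expect_identical(back$atom_name, atoms$atom_name)
  expect_identical(back$residue_number, atoms$residue_number)
  expect_identical(back$chain_id, atoms$chain_id)
  expect_equal(back$x, atoms$x, tolerance = 1e-9)  # both at 3-decimal grid
  expect_equal(back$z, atoms$z, tolerance = 1e-9)
})

test_that("ideal helix shows the one-turn i+/-3, i+/-4 side-chain pattern", {
  # bulky residues one turn away from the center; glycine immediately
  # adjacent so nearest-neighbor side chains cannot contribute
  pat <- rep("LEU", 15); pat[c(6, 7, 9, 10)] <- "GLY"
  atoms <- parse_coordinates(synth_helix_pdb(15, pat))
  rep <- neighbor_residues(atoms, "A", 8, 5.5)
  expect_setequal(rep$partners$residue_number, c(4, 5, 11, 12))
  expect_true(all(rep$partners$scope == "intra_chain"))
  expect_true(all(rep$partners$min_dist <= 5.5))

  # poly-Leu helix still finds the one-turn partners
  atoms2 <- parse_coordinates(synth_helix_pdb(15, "LEU"))
  rep2 <- neighbor_residues(atoms2, "A", 8, 5.5)
  expect_true(all(c(4, 5, 11, 12) %in% rep2$partners$residue_number))
  expect_error(neighbor_residues(atoms2, "A", 99), "lookup")
})

test_that("two glycines have no side-chain neighborhood", {
  atoms <- parse_coordinates(synth_helix_pdb(9, "GLY"))
  rep <- neighbor_residues(atoms, "A", 5, 5.5)
  expect_identical(nrow(rep$partners), 0L)
})

test_that("neighbor detection equals the brute-force all-pairs oracle", {
  pats <- list("LEU", "ILE", "THR", c("LEU", "ALA"), c("ILE", "GLY", "THR"),
               c("VAL", "SER"))
  set.seed(12)
  cases <- 0
  for (i in 1:20) {
    pat <- pats[[1 + (i %% length(pats))]]
    chains <- 1 + (i %% 2)
    pdb <- synth_helix_pdb(10 + (i %% 5), pat, chains = chains,
                           axis_sep = stats::runif(1, 7, 14),
                           chi1 = sample(c(-60, 60, 180), 1),
                           twist = stats::runif(1, 95, 105))
    atoms <- parse_coordinates(pdb)
    ctr <- sample(3:8, 1)
    got <- neighbor_residues(atoms, "A", ctr, 5.5)$partners
    want <- neighbors_brute(atoms, "A", ctr, 5.5)
    expect_identical(paste(got$chain_id, got$residue_number),
                     paste(want$chain_id, want$residue_number))
    expect_equal(got$min_dist, want$min_dist, tolerance = 1e-12)
    cases <- cases + nrow(got)
  }
  expect_gt(cases, 20)  # the fixtures actually exercised contacts
})

test_that("contact detection is symmetric and order-invariant", {
  pdb <- synth_helix_pdb(13, c("LEU", "THR"), chains = 2, axis_sep = 8.5)
  atoms <- parse_coordinates(pdb)
  repA <- neighbor_residues(atoms, "A", 7, 5.5)
  for (i in seq_len(nrow(repA$partners))) {
    p <- repA$partners[i, ]
    back <- neighbor_residues(atoms, p$chain_id, p$residue_number, 5.5)
    j <- back$partners$chain_id == "A" & back$partners$residue_number == 7
    expect_true(any(j))
    expect_equal(back$partners$min_dist[j], p$min_dist, tolerance = 1e-12)
  }
  set.seed(3)
  shuf <- atoms[sample(nrow(atoms)), ]
  repS <- neighbor_residues(shuf, "A", 7, 5.5)
  expect_identical(repS$partners$residue_number, repA$partners$residue_number)
  expect_equal(repS$partners$min_dist, repA$partners$min_dist, tolerance = 1e-12)
})

test_that("classification thresholds behave on constructed pairs", {
  mk <- function(serial, name, res, rn, x, el)
    data.frame(serial = serial, atom_name = name, alt_loc = " ",
               residue_name = res, chain_id = "A", residue_number = rn,
               x = x, y = 0, z = 0, occupancy = 1, element = el,
               stringsAsFactors = FALSE)
  # Thr OG1 3.0 A from the partner's backbone carbonyl O -> hbond (the
  # partner needs a side-chain atom in range for the 5.5 A neighborhood,
  # but classification then sees backbone O as an acceptor)
  atoms <- rbind(
    mk(1, "CB", "THR", 1, 0, "C"), mk(2, "OG1", "THR", 1, 1.4, "O"),
    mk(3, "O", "ALA", 2, 4.4, "O"), mk(4, "CB", "ALA", 2, 5.4, "C"))
  rep <- classify_contacts(neighbor_residues(atoms, "A", 1, 5.5), atoms)
  expect_identical(nrow(rep$partners), 1L)
  expect_match(rep$partners$contact_class, "hbond")

  # Thr CG2 4.0 A from Leu CD1 -> hydrophobic
  atoms2 <- rbind(
    mk(1, "CB", "THR", 1, 0, "C"), mk(2, "CG2", "THR", 1, 1.5, "C"),
    mk(3, "CD1", "LEU", 2, 5.5, "C"), mk(4, "CB", "LEU", 2, 7, "C"))
  rep2 <- classify_contacts(neighbor_residues(atoms2, "A", 1, 5.5), atoms2)
  expect_identical(rep2$partners$contact_class, "hydrophobic")

  # 5.0 A apart: proximal only
  atoms3 <- rbind(
    mk(1, "CB", "ALA", 1, 0, "C"), mk(2, "CB", "ALA", 2, 5.0, "C"))
  rep3 <- classify_contacts(neighbor_residues(atoms3, "A", 1, 5.5), atoms3)
  expect_identical(rep3$partners$contact_class, "proximal_only")
})

test_that("Ala -> Thr mutation: geometry, reversal, and contact gain", {
  pat <- rep("LEU", 15); pat[c(6, 7, 9, 10)] <- "GLY"; pat[8] <- "ALA"
  atoms <- parse_coordinates(synth_helix_pdb(15, pat))
  thr <- mutate_ala_thr(atoms, "A", 8)
  t8 <- thr[thr$residue_number == 8, ]
  expect_identical(t8$residue_name[1], "THR")
  xyz <- function(df, nm) unlist(df[df$atom_name == nm, c("x", "y", "z")])
  expect_equal(sqrt(sum((xyz(t8, "OG1") - xyz(t8, "CB"))^2)), 1.43,
               tolerance = 1e-3)
  expect_equal(sqrt(sum((xyz(t8, "CG2") - xyz(t8, "CB"))^2)), 1.52,
               tolerance = 1e-3)

  back <- mutate_ala_thr(thr, "A", 8)
  expect_identical(back$atom_name, atoms$atom_name)
  expect_identical(back[c("x", "y", "z")], atoms[c("x", "y", "z")])
  expect_identical(back$residue_name, atoms$residue_name)

  expect_error(mutate_ala_thr(atoms, "A", 4), "argument")  # LEU site

  # the built Thr reaches at least one residue the Ala could not, and the
  # classified (hbond/hydrophobic) partner count strictly increases
  n_class <- function(a) {
    r <- classify_contacts(neighbor_residues(a, "A", 8, 5.5), a)
    sum(r$partners$contact_class != "proximal_only")
  }
  expect_gt(nrow(neighbor_residues(thr, "A", 8, 5.5)$partners),
            nrow(neighbor_residues(atoms, "A", 8, 5.5)$partners) - 1)
  expect_gt(n_class(thr), n_class(atoms))
})

test_that("interface contacts across a two-helix dimer", {
  far <- parse_coordinates(synth_helix_pdb(15, "ALA", chains = 2, axis_sep = 12))
  expect_identical(sum(vapply(interface_contacts(far, 8),
                              function(r) nrow(r$partners), 0L)), 0L)
  near <- parse_coordinates(synth_helix_pdb(15, "ALA", chains = 2, axis_sep = 8))
  n_near <- vapply(interface_contacts(near, 8), function(r) nrow(r$partners), 0L)
  expect_true(all(n_near >= 1))
  single <- parse_coordinates(synth_helix_pdb(15, "ALA"))
  expect_error(interface_contacts(single, 8), "single-chain")

  # Thr centers give at least as many classified inter-chain contacts as Ala
  thr2 <- mutate_ala_thr(mutate_ala_thr(near, "A", 8), "B", 8)
  n_cls <- function(reps) sum(vapply(reps, function(r)
    sum(r$partners$contact_class != "proximal_only"), 0L))
  expect_gte(n_cls(interface_contacts(thr2, 8)),
             n_cls(interface_contacts(near, 8)))
})
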