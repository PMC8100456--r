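test_that("coordinate tables load with uniform priors and are deterministic", {
  path <- withr::local_tempfile(fileext = ".dat")
  write_table_fixture(path)
  ens <- load_ensemble(path, format = "table")
  expect_s3_class(ens, "conformational_ensemble")
  expect_equal(n_frames(ens), 3)
  expect_equal(ens$n_residues, 5)
  expect_equal(ens$prior_weights, rep(1 / 3, 3))
  ens2 <- load_ensemble(path, format = "table")
  expect_identical(ens$coords, ens2$coords)
})

test_that("a frame with a missing bead is rejected naming the frame", {
  path <- withr::local_tempfile(fileext = ".dat")
  write_table_fixture(path, drop_bead_in_frame = 2)
  expect_error(load_ensemble(path, format = "table"), "frame 2")
})

test_that("ensemble table write/read round-trips coordinates", {
  ens <- generate_chain_ensemble(12, 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".dat")
  write_ensemble_table(ens, path)
  back <- load_ensemble(path, format = "table")
  expect_equal(back$coords, ens$coords, tolerance = 1e-12)
})

test_that("multi-model PDB files map to one C-alpha bead per residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(serial, name, resname, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resname, resno, x, y, z)
  }
  model <- function(k, shift) {
    c(sprintf("MODEL     %4d", k),
      atom(1, "N", "ALA", 1, shift, 0, 0),
      atom(2, "CA", "ALA", 1, shift + 1, 0, 0),
      atom(3, "CA", "GLY", 2, shift + 4.8, 0, 0),
      atom(4, "CA", "SER", 3, shift + 8.6, 0, 0),
      "ENDMDL")
  }
  writeLines(c(model(1, 0), model(2, 10), "END"), path)
  ens <- load_ensemble(path, format = "pdb")
  expect_equal(n_frames(ens), 2)
  expect_equal(ens$n_residues, 3)
  expect_equal(ens$bead_labels$resname, c("ALA", "GLY", "SER"))
  # C-alpha of residue 1, model 2 is at x = 11
  expect_equal(frame_coords(ens, 2)[1, 1], 11)
  # bead weights follow glycine-normalized residue electron counts
  expect_equal(ens$bead_weights,
               unname(residue_electron_counts(c("ALA", "GLY", "SER"))))
})

test_that("weights round-trip normalized to 12 significant digits", {
  path <- withr::local_tempfile(fileext = ".dat")
  save_weights(c(0.2, 0.3, 0.5), path)
  w <- load_weights(path)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, c(0.2, 0.3, 0.5), tolerance = 1e-12)
  # unnormalized stored weights come back normalized
  writeLines(c("# raw", "2", "3", "5"), path)
  expect_message(w2 <- load_weights(path), "renormalizing")
  expect_equal(w2, c(0.2, 0.3, 0.5), tolerance = 1e-12)
})

test_that("SAXS profiles parse headers, reject bad files, and round-trip", {
  path <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.01, 0.20, length.out = 19)
  I <- 100 * exp(-q^2 * 300)
  writeLines(c("# q I err", "q I err", sprintf("%.8g %.8g %.8g", q, I, 0.01 * I)),
             path)
  p <- load_saxs_profile(path)
  expect_equal(nrow(p), 19)
  expect_equal(p$q, q, tolerance = 1e-7)

  out <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(p, out)
  p2 <- load_saxs_profile(out)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-12)

  writeLines(c("0.01 10 0.1"), path)
  expect_error(load_saxs_profile(path), "fewer than 2")
  writeLines(c("0.02 10 0.1", "0.01 11 0.1"), path)
  expect_error(load_saxs_profile(path), "increasing")
  writeLines(c("0.01 10 0.1", "0.02 9 -1", "0.03 8 0.1"), path)
  expect_warning(p3 <- load_saxs_profile(path), "non-positive sigma")
  expect_equal(nrow(p3), 2)
})

test_that("re-binning pools by inverse variance on the requested range", {
  set.seed(5)
  q <- seq(0.005, 0.4, length.out = 120)
  I <- 50 * exp(-q^2 * 250)
  p <- scattering_profile(q, I, 0.02 * I)
  rb <- rebin_profile(p, 19, 0.01, 0.20)
  expect_equal(nrow(rb), 19)
  expect_gte(min(rb$q), 0.01)
  expect_lte(max(rb$q), 0.20)

  # one point per bin leaves a uniform-grid profile unchanged
  pu <- scattering_profile(seq(0.02, 0.1, by = 0.01), 1:9, rep(0.5, 9))
  same <- rebin_profile(pu, 9, 0.02, 0.10)
  expect_equal(same$intensity, pu$intensity, tolerance = 1e-12)
  expect_equal(same$q, pu$q, tolerance = 1e-12)

  # two equal-sigma points: arithmetic mean, sigma smaller by 1/sqrt(2)
  p2 <- scattering_profile(c(0.010, 0.012, 0.03), c(4, 6, 5), c(0.2, 0.2, 0.2))
  rb2 <- rebin_profile(p2, 2, 0.01, 0.03)
  expect_equal(rb2$intensity[1], 5)
  expect_equal(rb2$sigma[1], 0.2 / sqrt(2))

  expect_error(rebin_profile(p2, 10, 0.01, 0.03), "empty")
})

test_that("PRE tables group label sites and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  sites <- c(24, 42, 62, 87, 103)
  tab <- do.call(rbind, lapply(sites, function(s) {
    data.frame(label_site = s, residue = c(10, 50, 120),
               ratio = c(0.2, 0.8, 0.95), error = 0.05)
  }))
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  d <- load_pre_table(path, n_residues = 140)
  expect_s3_class(d, "pre_dataset")
  expect_equal(sort(unique(d$label_site)), sites)

  tab_dup <- rbind(tab, tab[1, ])
  utils::write.table(tab_dup, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_pre_table(path), "duplicate")

  tab_bad <- tab
  names(tab_bad)[1] <- "site"
  utils::write.table(tab_bad, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_pre_table(path), "label_site")

  expect_error(pre_dataset(tab, n_residues = 50), "outside protein range")
})
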