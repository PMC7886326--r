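# Brute-force contact oracle: all residue pairs, all atom pairs.
brute_contacts <- function(model, cutoff, min_sep) {
  at <- model$atoms
  out <- list()
  for (i in seq_len(model$n_res)) {
    for (j in seq_len(model$n_res)) {
      if (j - i < min_sep) next
      ai <- at[at$res_index == i, ]
      aj <- at[at$res_index == j, ]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) {
        d <- sqrt((ai$x[p] - aj$x)^2 + (ai$y[p] - aj$y)^2 + (ai$z[p] - aj$z)^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

test_that("contact finding matches the brute-force all-pairs oracle", {
  for (fold in c("helix", "hairpin", "domain")) {
    m <- synth_structure(24, fold)
    got <- find_contacts(m, cutoff = 6, min_separation = 1)
    want <- brute_contacts(m, 6, 1)
    expect_equal(got[, c("i", "j")], want, info = fold, ignore_attr = TRUE)
  }
  # separation threshold respected
  m <- synth_structure(30, "helix")
  far <- find_contacts(m, 6, 4)
  expect_true(all(far$separation >= 4))
  expect_error(find_contacts(m, -1), "positive")
})

test_that("relative contact order follows the normalized mean-separation formula", {
  # hand case: 10 residues, single contact (1, 6)
  at <- tibble::tibble(
    res_index = 1:10, atom = "CA",
    x = c(0, 10, 20, 30, 40, 3, 60, 70, 80, 90),
    y = c(0, 0, 0, 0, 0, 4, 0, 0, 0, 0), z = 0
  )
  m <- structure_model(at)
  cs <- find_contacts(m, 6, 1)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$separation, 5)
  rco <- relative_contact_order(m)
  expect_equal(rco$rco_percent, 100 * 5 / 10)
  # all-adjacent contacts: RCO = 100 / L
  line <- structure_model(tibble::tibble(
    res_index = 1:8, atom = "CA", x = 5 * (0:7), y = 0, z = 0
  ))
  rco_line <- relative_contact_order(line)
  expect_equal(rco_line$rco_percent, 100 / 8)
  # no contacts -> flagged undefined
  sparse <- structure_model(tibble::tibble(
    res_index = 1:4, atom = "CA", x = 100 * (0:3), y = 0, z = 0
  ))
  expect_warning(un <- relative_contact_order(sparse), "undefined")
  expect_true(is.na(un$rco_percent))
})

test_that("RCO is invariant under rigid-body transformation", {
  m <- synth_structure(36, "domain")
  base <- relative_contact_order(m)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% R
  moved <- structure_model(tibble::tibble(
    res_index = m$atoms$res_index, atom = m$atoms$atom,
    x = xyz[, 1] + 12.3, y = xyz[, 2] - 4.5, z = xyz[, 3] + 99
  ))
  expect_equal(relative_contact_order(moved), base)
})

test_that("a long-range contact raises RCO relative to a short-range one", {
  mk <- function(j_close) {
    x <- 10 * (0:9)
    y <- rep(40, 10)
    y[1] <- 0
    x[j_close] <- 3
    y[j_close] <- 4 # distance 5 from residue 1; everything else is far
    structure_model(tibble::tibble(
      res_index = 1:10, atom = "CA", x = x, y = y, z = 0
    ))
  }
  near <- mk(4) # contact (1,4)
  far <- mk(9) # contact (1,9)
  expect_equal(relative_contact_order(near)$n_contacts, 1)
  expect_equal(relative_contact_order(far)$n_contacts, 1)
  expect_gt(
    relative_contact_order(far)$rco_percent,
    relative_contact_order(near)$rco_percent
  )
})

test_that("PDB files round-trip through read_structure (first model, one chain)", {
  # write a small synthetic two-model PDB by hand and read it back
  m <- synth_structure(6, "helix")
  fmt_atom <- function(serial, resno, x, y, z) {
    sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, resno, x, y, z
    )
  }
  lines <- c("MODEL        1")
  for (i in seq_len(6)) {
    a <- m$atoms[i, ]
    lines <- c(lines, fmt_atom(i, i, a$x, a$y, a$z))
  }
  lines <- c(lines, "ENDMDL", "MODEL        2")
  for (i in seq_len(6)) {
    a <- m$atoms[i, ]
    lines <- c(lines, fmt_atom(i, i, a$x + 50, a$y, a$z))
  }
  lines <- c(lines, "ENDMDL", "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  got <- read_structure(tmp)
  expect_equal(got$n_res, 6)
  expect_equal(got$atoms$x, m$atoms$x, tolerance = 1e-3)
  got2 <- read_structure(tmp, model = 2)
  expect_equal(got2$atoms$x, m$atoms$x + 50, tolerance = 1e-3)
  expect_error(read_structure(tmp, model = 3), "file has")
})
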