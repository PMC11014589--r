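test_that("crowding distances follow the Bouma law", {
  expect_equal(radial_crowding_distance(bouma_params(0.34, phi0 = 0), 10), 3.4)
  p <- bouma_params(0.22, phi0 = 0.24, a = 2)
  expect_equal(radial_crowding_distance(p, 0), 0.22 * 0.24)
  expect_equal(radial_crowding_distance(p, 5), 1.1528)
  expect_equal(tangential_crowding_distance(p, 5), 0.5764)
  expect_equal(
    tangential_crowding_distance(bouma_params(0.34, phi0 = 0, a = 2), 10), 1.7
  )
  # a = 1 is the isotropic case
  iso <- bouma_params(0.3, a = 1)
  phis <- c(0, 2.5, 5, 10)
  expect_equal(tangential_crowding_distance(iso, phis),
               radial_crowding_distance(iso, phis))
  # strictly increasing in eccentricity
  expect_true(all(diff(radial_crowding_distance(p, seq(0, 10, 0.5))) > 0))
  expect_error(radial_crowding_distance(p, -1), "negative")
})

test_that("letter density is the reciprocal crowding-zone area", {
  expect_equal(letter_density(bouma_params(1, phi0 = 0, a = 1), 1), 1)
  expect_equal(letter_density(bouma_params(0.34, phi0 = 0.24, a = 2), 10),
               2 / (0.34^2 * 10.24^2))
  # density scales as b^-2
  d1 <- letter_density(bouma_params(0.2, a = 3), 4)
  d2 <- letter_density(bouma_params(0.4, a = 3), 4)
  expect_equal(d1 / d2, 4)
  # strictly decreasing in eccentricity, singular at phi + phi0 = 0
  expect_true(all(diff(letter_density(bouma_params(0.3), seq(0, 10, 1))) < 0))
  expect_error(letter_density(bouma_params(0.3, phi0 = 0), 0), "singular")
})

test_that("closed-form letter count reproduces the worked values", {
  expect_equal(round(uncrowded_letters(bouma_params(0.34))), 302)
  expect_equal(uncrowded_letters(bouma_params(1)), 34.9, tolerance = 0.05 / 34.9)
  # lambda vanishes with the field
  expect_lt(uncrowded_letters(bouma_params(0.34), phi_max = 1e-8), 1e-6)
  expect_error(uncrowded_letters(bouma_params(0.3, phi0 = 0)),
               "diverges logarithmically")
})

test_that("closed form matches the quadrature oracle over a parameter grid", {
  set.seed(42)
  for (i in 1:25) {
    p <- bouma_params(runif(1, 0.1, 1), phi0 = runif(1, 0.05, 1),
                      a = runif(1, 1, 4))
    phi_max <- runif(1, 2, 20)
    closed <- uncrowded_letters(p, phi_max)
    numeric <- uncrowded_letters_numeric(p, phi_max)
    expect_equal(closed, numeric, tolerance = 1e-6)
  }
  # worked value through the independent route too
  expect_equal(uncrowded_letters_numeric(bouma_params(0.34)), 301.8598,
               tolerance = 1e-6)
  expect_equal(uncrowded_letters_numeric(bouma_params(1)), 34.9,
               tolerance = 0.05 / 34.9)
})

test_that("lambda scales exactly as b^-2 and is monotone in every constant", {
  bs <- c(0.1, 0.22, 0.34, 0.7, 1.3)
  lam_b2 <- vapply(bs, function(b) uncrowded_letters(bouma_params(b)) * b^2,
                   numeric(1))
  expect_equal(lam_b2, rep(lam_b2[1], length(bs)))
  # prefactor at the default constants is 34.9 to 3 significant figures
  expect_equal(signif(lam_b2[1], 3), 34.9)
  lam <- function(b = 0.3, phi0 = 0.24, a = 2, phi_max = 10) {
    uncrowded_letters(bouma_params(b, phi0 = phi0, a = a), phi_max)
  }
  expect_true(all(diff(vapply(1:5, function(m) lam(phi_max = 2 * m),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(1:4, function(a) lam(a = a), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.1, 0.3, 0.6), function(b) lam(b = b),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0.1, 0.24, 0.5), function(p0) lam(phi0 = p0),
                              numeric(1))) < 0))
})

test_that("sensitivity multipliers follow the closed form's structure", {
  p <- bouma_params(0.3)
  tab <- lambda_sensitivity(p, a_values = 4, phi0_values = c(0.24, 0.5))
  a_row <- tab[tab$parameter == "a", ]
  expect_equal(a_row$lambda_multiplier, 2)
  expect_equal(a_row$c_multiplier, 1 / sqrt(2))
  id_row <- tab[tab$parameter == "phi0" & tab$value == 0.24, ]
  expect_equal(id_row$lambda_multiplier, 1)
  # phi0 change scales lambda by the ratio of the bracketed log terms,
  # computed here independently of the package's closed form
  bracket <- function(phi0) log(1 + 10 / phi0) - 1 / (1 + phi0 / 10)
  alt_row <- tab[tab$parameter == "phi0" & tab$value == 0.5, ]
  expect_equal(alt_row$lambda_multiplier, bracket(0.5) / bracket(0.24))
  expect_equal(alt_row$c_multiplier, (bracket(0.5) / bracket(0.24))^(-0.5))
})

test_that("letter layout packs the field at threshold spacing", {
  p <- bouma_params(0.34)
  expect_identical(nrow(letter_layout(p, angle_range = c(1, 1))), 0L)
  full <- letter_layout(p)
  lambda <- uncrowded_letters(p)
  expect_lt(abs(nrow(full) - lambda) / lambda, 0.1)
  # b^-2 scaling survives discretisation
  half_b <- letter_layout(bouma_params(0.17))
  expect_equal(nrow(half_b) / nrow(full), 4, tolerance = 0.1)
  # adjacent rings sit one local radial crowding distance apart
  rings <- sort(unique(full$eccentricity_deg))
  gaps <- diff(rings)
  mids <- (rings[-1] + rings[-length(rings)]) / 2
  expect_equal(gaps, radial_crowding_distance(p, mids), tolerance = 0.02)
  # sector restriction respected
  sec <- letter_layout(p, ecc_range = c(3, 8.5),
                       angle_range = c(-25, 25) * pi / 180)
  expect_true(all(sec$eccentricity_deg >= 3 & sec$eccentricity_deg <= 8.5))
  expect_true(all(sec$angle_rad > -25 * pi / 180 &
                    sec$angle_rad < 25 * pi / 180))
})
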