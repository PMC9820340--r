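BOHR <- 0.529177210903

test_that("the hydrogen proatom is the exact ground-state density", {
  mod <- default_proatom_model()
  expect_equal(proatom_density(mod, "H", 0.5), exp(-1) / pi, tolerance = 1e-12)
  ## every proatom is monotonically decreasing and integrates to Z
  for (el in names(mod)) {
    r <- seq(0.01, 10, by = 0.01)
    rho <- proatom_density(mod, el, r)
    expect_true(all(diff(rho) < 0))
    total <- sum(4 * pi * r^2 * rho) * 0.01
    z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)[[el]]
    expect_equal(total, z, tolerance = 0.01)
  }
})

test_that("promolecular density is the superposition of proatom fields", {
  g <- grid_from_box(c(-1.3, -1.1, -0.9), c(1.3, 1.1, 0.9), spacing = 0.25)
  f_pair <- promolecular_fields(two_atoms(sep = 1.4), g)
  f_a <- promolecular_fields(translate_structure(h_atom(), c(-0.7, 0, 0)), g)
  f_b <- promolecular_fields(translate_structure(h_atom(), c(0.7, 0, 0)), g)
  expect_equal(f_pair$rho, f_a$rho + f_b$rho, tolerance = 1e-12)
  expect_equal(f_pair$grad, f_a$grad + f_b$grad, tolerance = 1e-12)
})

test_that("grid s-values match the single-exponential closed form", {
  ## single-term proatom: s(r) = 1 / (2 (3 pi^2)^(1/3) zeta rho(r)^(1/3))
  mod <- default_proatom_model()
  g <- grid_from_box(c(0.13, 0.11, 0.09), c(1.6, 1.6, 1.6), spacing = 0.15)
  f <- promolecular_fields(h_atom(), g, mod)
  r <- sqrt(rowSums((grid_points(g) / BOHR)^2))
  zeta <- mod$H$zeta
  rho_cf <- mod$H$c * exp(-r / zeta)
  s_cf <- 1 / (2 * (3 * pi^2)^(1 / 3) * zeta * rho_cf^(1 / 3))
  expect_equal(f$rho, rho_cf, tolerance = 1e-10)
  expect_lt(max(abs(f$s - s_cf)), 1e-8)
})

test_that("analytic derivatives match central finite differences", {
  set.seed(77)
  st <- two_atoms(c("C", "O"), sep = 2.3)
  h <- 1e-3                                 # Angstrom step
  max_g <- 0
  max_h <- 0
  for (i in 1:30) {
    ## keep test points off the steep core-shell region where the FD
    ## truncation error itself exceeds the tolerance
    repeat {
      p <- runif(3, -2, 2)
      if (min(sqrt(colSums((t(st$xyz) - p)^2))) > 0.7) break
    }
    g <- volumetric_grid(p, diag(rep(h, 3)), c(3L, 3L, 3L))
    f <- suppressMessages(promolecular_fields(st, g))
    ## storage order: z fastest; center point is index 14 (i=j=k=1)
    hb <- h / BOHR
    num_grad <- c(f$rho[23] - f$rho[5], f$rho[17] - f$rho[11],
                  f$rho[15] - f$rho[13]) / (2 * hb)
    max_g <- max(max_g, abs(num_grad - f$grad[14, ]))
    num_hxx <- (f$rho[23] - 2 * f$rho[14] + f$rho[5]) / hb^2
    num_hyy <- (f$rho[17] - 2 * f$rho[14] + f$rho[11]) / hb^2
    max_h <- max(max_h, abs(num_hxx - f$hessian[14, 1]),
                 abs(num_hyy - f$hessian[14, 2]))
  }
  expect_lt(max_g, 1e-6)
  expect_lt(max_h, 1e-6)
})

test_that("the midpoint of a homonuclear pair is a zero-gradient saddle", {
  st <- two_atoms(sep = 2.0)
  g <- volumetric_grid(c(0, 0, 0), diag(rep(0.1, 3)), c(1L, 1L, 1L))
  f <- promolecular_fields(st, g)
  expect_equal(f$s, 0)
  expect_lt(f$lambda2, 0)                  # attractive signature at the saddle
  expect_lt(f$signed_rho, 0)
  ## lambda2 agrees with a full eigendecomposition
  H <- matrix(0, 3, 3)
  H[1, 1] <- f$hessian[1]; H[2, 2] <- f$hessian[2]; H[3, 3] <- f$hessian[3]
  H[1, 2] <- H[2, 1] <- f$hessian[4]
  H[1, 3] <- H[3, 1] <- f$hessian[5]
  H[2, 3] <- H[3, 2] <- f$hessian[6]
  expect_equal(f$lambda2, sort(eigen(H, symmetric = TRUE)$values)[2],
               tolerance = 1e-6)
})

test_that("reduced gradient follows the k^(-1/3) density-scaling law", {
  set.seed(13)
  rho <- runif(50, 1e-3, 1)
  grad <- matrix(rnorm(150), 50, 3)
  s1 <- reduced_gradient(rho, grad)
  for (k in c(0.5, 2, 10)) {
    s2 <- reduced_gradient(k * rho, k * grad)
    expect_equal(s2, k^(-1 / 3) * s1, tolerance = 1e-12)
  }
  expect_error(reduced_gradient(c(1, 0), matrix(0, 2, 3)), "positive")
})

test_that("an isolated atom shows no low-gradient interaction region", {
  ## away from the nucleus s grows monotonically; a grid excluding a small
  ## nuclear ball retains nothing below s_max
  g <- grid_from_box(c(0.2, 0.2, 0.2), c(2, 2, 2), spacing = 0.2)
  f <- promolecular_fields(h_atom(), g)
  expect_warning(cl <- classify_nci(f), "no grid points retained")
  expect_identical(sum(cl$counts), 0L)
  expect_identical(cl$n_retained, 0L)
})

test_that("two nearby atoms develop a low-s region at the midpoint", {
  st <- two_atoms(c("C", "C"), sep = 2.0)
  g <- grid_from_box(c(-2, -1.5, -1.5), c(2, 1.5, 1.5), spacing = 0.15)
  f <- suppressMessages(promolecular_fields(st, g))
  cl <- classify_nci(f)
  expect_gt(cl$counts[["attractive"]] + cl$counts[["vdw"]], 0L)
  expect_identical(sum(cl$counts), cl$n_retained)   # categories partition
  ## a low-s basin sits at the bond midpoint plane (s is also small right at
  ## the nuclei, so only assert existence near the midpoint)
  low <- c(cl$indices$attractive, cl$indices$vdw)
  expect_true(any(abs(grid_points(g)[low, 1]) < 0.3))
})

test_that("stacked rings produce a van der Waals band between the faces", {
  st <- combine_structures(make_ring(), translate_structure(make_ring(), c(0, 0, 3.4)))
  nci <- suppressMessages(
    interfacial_nci(st, "resid 1", margin = 1.0, spacing = 0.25))
  expect_gt(nci$classification$counts[["vdw"]], 0L)
  z_vdw <- grid_points(nci$grid$geometry)[nci$classification$indices$vdw, 3]
  expect_true(any(abs(z_vdw - 1.7) < 0.6))
})

test_that("interfacial grids degrade gracefully and round-trip as cubes", {
  ## margin 0 around a single atom still yields a usable >= 2^3 grid
  nci <- suppressMessages(suppressWarnings(
    interfacial_nci(h_atom(), 1L, margin = 0, spacing = 0.15)))
  expect_true(all(nci$grid$geometry$shape >= 2L))
  st <- two_atoms(c("C", "N"), sep = 2.2)
  out <- suppressMessages(interfacial_nci(st, 1:2, margin = 1, spacing = 0.3))
  path <- withr::local_tempfile(fileext = ".cube")
  write_grid(nci_field_grid(out$grid, "signed_rho"), st, path)
  rt <- read_grid(path)
  expect_equal(rt$grid$values, out$grid$signed_rho, tolerance = 1e-4)
  expect_identical(rt$grid$shape, out$grid$geometry$shape)
})

test_that("missing proatom parameters are reported by element", {
  st <- two_atoms(c("C", "Fe"), sep = 2.0)
  expect_error(promolecular_fields(st, grid_from_box(c(-1, -1, -1), c(1, 1, 1))),
               "Fe")
})
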