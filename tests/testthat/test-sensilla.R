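make_map <- function(df, ...) sensilla_map(df, ...)

test_that("density maps conserve kernel mass for interior points", {
  # empty map -> all-zero grid
  empty <- make_map(tibble::tibble(x_norm = numeric(0), y_norm = numeric(0),
                                   type = character(0)))
  g0 <- density_map(empty, "trichoid")
  expect_true(all(g0$z == 0))

  cell <- 1 / 200 * 1 / 100
  # single interior sensillum integrates to ~1
  one <- make_map(tibble::tibble(x_norm = 0.5, y_norm = 0.5,
                                 type = "basiconic"))
  g1 <- density_map(one, "basiconic")
  expect_equal(sum(g1$z) * cell, 1, tolerance = 0.01)

  # n interior sensilla integrate to ~n
  set.seed(21)
  n <- 150
  pts <- make_map(tibble::tibble(
    x_norm = runif(n, 0.2, 0.8), y_norm = runif(n, 0.25, 0.75),
    type = "trichoid"))
  gn <- density_map(pts, "trichoid")
  expect_equal(sum(gn$z) * cell, n, tolerance = 0.01 * n)

  # edge kernels are clipped, not renormalized: mass < 1
  edge <- make_map(tibble::tibble(x_norm = 0, y_norm = 0, type = "clavate"))
  ge <- density_map(edge, "clavate")
  expect_lt(sum(ge$z) * cell, 0.5)

  expect_error(density_map(one, "basiconic", sigma_x = -1),
               class = "olfactomap_validation_error")
})

test_that("sensilla map validation rejects bad coordinates and types", {
  expect_error(make_map(tibble::tibble(x_norm = 1.2, y_norm = 0.5,
                                       type = "trichoid")),
               class = "olfactomap_validation_error")
  expect_error(make_map(tibble::tibble(x_norm = 0.5, y_norm = 0.5,
                                       type = "styloconic")),
               class = "olfactomap_validation_error")
  expect_error(make_map(tibble::tibble(x = 0.5, y = 0.5, type = "trichoid")),
               class = "olfactomap_validation_error")
})

test_that("dominance index follows its closed form, bounds and antisymmetry", {
  # build grids with controlled densities via uniform point sets
  mk_grid <- function(v) {
    structure(list(x = seq(0.05, 0.95, by = 0.1),
                   y = seq(0.1, 0.9, by = 0.2),
                   z = matrix(v, 10, 5), type = "synthetic",
                   n_points = NA, sigma_x = 0.02, sigma_y = 0.05),
              class = "density_grid")
  }
  prof <- dominance_profile(mk_grid(2), mk_grid(1), mk_grid(1))
  expect_true(all(prof$dominance == 0.5))
  # only trichoid -> -1; no trichoid -> +1
  expect_true(all(dominance_profile(mk_grid(0), mk_grid(0),
                                    mk_grid(3))$dominance == -1))
  expect_true(all(dominance_profile(mk_grid(1), mk_grid(0.5),
                                    mk_grid(0))$dominance == 1))
  # zero total density is undefined, not 0
  expect_true(all(is.na(dominance_profile(mk_grid(0), mk_grid(0),
                                          mk_grid(0))$dominance)))
  # antisymmetry under exchanging (b + c) with t
  set.seed(5)
  a <- mk_grid(runif(50)); b <- mk_grid(runif(50)); c3 <- mk_grid(runif(50))
  p1 <- dominance_profile(a, b, c3)$dominance
  zero <- mk_grid(0)
  bc <- mk_grid(a$z + b$z)
  p2 <- dominance_profile(c3, zero, bc)$dominance
  expect_equal(p1, -p2, tolerance = 1e-12)
  expect_true(all(abs(p1) <= 1))
  # mismatched lattices rejected
  g2 <- mk_grid(1); g2$x <- g2$x + 0.01
  expect_error(dominance_profile(g2, mk_grid(1), mk_grid(1)),
               class = "olfactomap_validation_error")
})

test_that("default synthetic maps yield a proximally-positive, decreasing dominance profile", {
  maps <- lapply(1:3, function(i) {
    simulate_sensilla(seed = 100 + i, individual = paste0("ind", i))
  })
  profs <- lapply(maps, dominance_profile_map)
  for (p in profs) {
    ok <- !is.na(p$dominance)
    rho <- cor(p$x_norm[ok], p$dominance[ok], method = "spearman")
    expect_lt(rho, -0.9)
  }
})

test_that("dominance profiles are stable across grid resolutions", {
  map <- simulate_sensilla(seed = 77)
  p200 <- dominance_profile_map(map, grid_res = c(200L, 100L))
  p400 <- dominance_profile_map(map, grid_res = c(400L, 100L))
  # compare on the coarse bin centres by averaging fine bins pairwise
  fine <- (p400$dominance[seq(1, 399, by = 2)] +
             p400$dominance[seq(2, 400, by = 2)]) / 2
  ok <- !is.na(p200$dominance) & !is.na(fine)
  expect_gt(mean(ok), 0.8)
  expect_lt(max(abs(p200$dominance[ok] - fine[ok])), 0.01 * 2)  # 1% of range
})

test_that("count summary reproduces published per-species arithmetic", {
  mk_ind <- function(counts, sp, ind) {
    pts <- purrr::map_dfr(names(counts), function(ty) {
      tibble::tibble(x_norm = runif(counts[[ty]], 0.05, 0.95),
                     y_norm = runif(counts[[ty]], 0.05, 0.95), type = ty)
    })
    pts$species <- sp; pts$individual <- ind
    sensilla_map(pts)
  }
  set.seed(1)
  ddem <- c(trichoid = 654, basiconic = 656, clavate = 312, coeloconic = 391)
  bzon <- c(trichoid = 642, basiconic = 271, clavate = 204, coeloconic = 174)
  maps <- list(mk_ind(ddem, "Ddem", "i1"), mk_ind(bzon, "Bzon", "i1"))
  smry <- count_summary(maps)
  dd <- smry[smry$species == "Ddem" & smry$statistic == "individual", ]
  expect_identical(as.integer(dd$total), 2013L)
  expect_identical(as.integer(dd$basiconic_clavate), 968L)
  expect_equal(dd$bc_t_ratio, 1.48, tolerance = 0.005)
  bz <- smry[smry$species == "Bzon" & smry$statistic == "individual", ]
  expect_identical(as.integer(bz$total), 1291L)
  expect_equal(bz$bc_t_ratio, 0.74, tolerance = 0.005)
  # totals equal the sum of morphotype counts exactly
  ind_rows <- smry[smry$statistic == "individual", ]
  expect_identical(ind_rows$total,
                   ind_rows$trichoid + ind_rows$basiconic +
                     ind_rows$clavate + ind_rows$coeloconic)
})

test_that("count summary handles single-morphotype maps and supplied areas", {
  one <- sensilla_map(tibble::tibble(
    x_norm = runif(25), y_norm = runif(25), type = "coeloconic",
    species = "X", individual = "i1"), face_area_mm2 = 0.05)
  smry <- count_summary(one)
  ind <- smry[smry$statistic == "individual", ]
  expect_identical(as.integer(ind$total), 25L)
  expect_identical(as.integer(ind$trichoid), 0L)
  expect_true(is.na(ind$bc_t_ratio))  # no trichoid: ratio undefined
  expect_equal(ind$density_total_mm2, 25 / 0.05)
})
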