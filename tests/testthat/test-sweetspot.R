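# Voxel-wise sweetspot mapping, score-based estimation, cluster extraction.

make_fields <- function(valarrays, affine = diag(4)) {
  lapply(seq_along(valarrays), function(i)
    efield_from_values(valarrays[[i]], affine, id = i))
}

test_that("fit_sweetspot computes masked voxel-wise Spearman R", {
  set.seed(17)
  shape <- c(6L, 6L, 6L)
  fields <- make_fields(replicate(15, array(abs(rnorm(prod(shape))), shape),
                                  simplify = FALSE))
  y <- rnorm(15)
  map <- fit_sweetspot(fields, y, thr = 0.5, fraction = 0.2)
  V <- vapply(fields, function(E) as.vector(E$grid$values), numeric(prod(shape)))
  counts <- rowSums(V >= 0.5)
  expect_identical(as.vector(map$mask), counts / 15 >= 0.2)
  # brute-force per-voxel rank correlation on the mask
  for (v in which(map$mask)[1:25])
    expect_allclose(map$rmap$values[v], oracle_spearman(V[v, ], y))
  expect_true(all(is.nan(map$rmap$values[!map$mask])))
  expect_error(fit_sweetspot(fields, rep(1, 15)), "zero outcome variance")
  expect_error(fit_sweetspot(fields[1:2], y[1:2]), "at least 3")
})

test_that("a voxel rank-matching outcomes gets R = 1", {
  shape <- c(3L, 3L, 3L)
  y <- c(5, 1, 9, 3, 7)
  fields <- make_fields(lapply(y, function(o) {
    a <- array(1, shape); a[2, 2, 2] <- 1 + o; a
  }))
  map <- fit_sweetspot(fields, y, thr = 0.5, fraction = 0.2)
  expect_equal(map$rmap$values[2, 2, 2], 1)
})

test_that("score_efield_map is the masked mean of E x R", {
  set.seed(18)
  shape <- c(5L, 5L, 5L)
  fields <- make_fields(replicate(10, array(abs(rnorm(125)) + 0.3, shape),
                                  simplify = FALSE))
  map <- fit_sweetspot(fields, rnorm(10), thr = 0.4, fraction = 0.3)
  E <- fields[[1]]
  midx <- which(map$mask)
  expect_allclose(score_efield_map(map, E),
                  mean(E$grid$values[midx] * map$rmap$values[midx]))
  # zero field on the mask scores 0; constant map scores the constant field
  z <- efield_from_values(array(0, shape))
  expect_equal(score_efield_map(map, z), 0)
  grid_mismatch <- efield_from_values(array(0, c(4, 4, 4)))
  expect_error(score_efield_map(map, grid_mismatch), "mismatch")
})

test_that("mirror equivariance and mirrored-map symmetry hold exactly", {
  set.seed(19)
  g <- make_grid(c(9L, 8L, 7L), 1.5)
  shape <- dim(g$values)
  fields <- make_fields(replicate(8, array(abs(rnorm(prod(shape))) + 0.2, shape),
                                  simplify = FALSE), affine = g$affine)
  y <- rnorm(8)
  map <- fit_sweetspot(fields, y, thr = 0.3, fraction = 0.25)
  flipped <- fit_sweetspot(lapply(fields, mirror_efield), y,
                           thr = 0.3, fraction = 0.25)
  expect_identical(flipped$rmap$values, map$rmap$values[rev(seq_len(shape[1])), , ])
  mm <- fit_sweetspot(fields, y, thr = 0.3, fraction = 0.25, mirrored = TRUE)
  expect_identical(mm$rmap$values, mm$rmap$values[rev(seq_len(shape[1])), , ])
})

test_that("extract_clusters reports components, peaks and centroids", {
  g <- make_grid(c(9L, 9L, 9L), 1)
  vals <- array(NaN, c(9, 9, 9))
  # one positive voxel on the right
  at <- world_to_voxel(voxel_grid(vals, g$affine), c(2, 0, 0))$ijk + 1L
  vals[at[1], at[2], at[3]] <- 0.8
  map <- structure(list(rmap = voxel_grid(vals, g$affine),
                        mask = !is.nan(vals), thr = 0.2, fraction = 0.2,
                        mirrored = FALSE), class = "sweetspot_map")
  rep1 <- extract_clusters(map)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$sign, "sweet")
  expect_equal(c(rep1$peak_x, rep1$peak_y, rep1$peak_z), c(2, 0, 0))
  expect_equal(c(rep1$cog_x, rep1$cog_y, rep1$cog_z), c(2, 0, 0))

  # two disjoint positive blobs -> two sweet clusters
  vals[at[1] - 3, at[2], at[3]] <- 0.5
  map$rmap <- voxel_grid(vals, g$affine); map$mask <- !is.nan(vals)
  rep2 <- extract_clusters(map)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$peak_R[1], 0.8)    # sorted by |peak R|

  expect_error(extract_clusters(structure(
    list(rmap = voxel_grid(array(NaN, c(2, 2, 2)), diag(4)),
         mask = array(FALSE, c(2, 2, 2))), class = "sweetspot_map")), "empty")
})

test_that("cluster labelling matches a brute-force flood fill", {
  set.seed(20)
  g <- make_grid(c(11L, 11L, 9L), 1)
  vals <- array(NaN, dim(g$values))
  blob <- array(runif(prod(dim(g$values))) < 0.18, dim(g$values))
  vals[blob] <- runif(sum(blob), 0.1, 0.9)
  map <- structure(list(rmap = voxel_grid(vals, g$affine), mask = blob,
                        thr = 0.2, fraction = 0.2, mirrored = FALSE),
                   class = "sweetspot_map")
  rep26 <- extract_clusters(map, connectivity = 26)
  # independent oracle: DFS flood fill over an explicit adjacency list built
  # from pairwise Chebyshev distances, per hemisphere
  xs <- stimmap:::grid_x_coords(map$rmap)
  oracle <- list()
  for (hemi in list(xs < 0, xs >= 0)) {
    sel <- which(blob & hemi & is.finite(vals) & vals > 0)
    ijk <- stimmap:::linear_to_ijk(dim(vals), sel)
    adj <- as.matrix(dist(ijk, method = "maximum")) <= 1
    seen <- rep(FALSE, length(sel))
    for (s in seq_along(sel)) {
      if (seen[s]) next
      comp <- s; stack <- s; seen[s] <- TRUE
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        nb <- which(adj[cur, ] & !seen)
        seen[nb] <- TRUE
        comp <- c(comp, nb); stack <- c(stack, nb)
      }
      r <- vals[sel[comp]]
      xyz <- voxel_to_world(map$rmap, ijk[comp, , drop = FALSE])
      oracle[[length(oracle) + 1]] <- list(
        n = length(comp),
        cog = colSums(xyz * abs(r)) / sum(abs(r)))
    }
  }
  sweet <- rep26[rep26$sign == "sweet", ]
  expect_setequal(sweet$n_voxels, vapply(oracle, `[[`, 0L, "n"))
  # weighted centroids agree (match clusters by size, which are unique here
  # with overwhelming probability; fall back to set comparison of rounded cogs)
  got_cogs <- sort(round(sweet$cog_x + 1000 * sweet$cog_y + 1e6 * sweet$cog_z, 6))
  exp_cogs <- sort(round(vapply(oracle, function(o) o$cog[1] + 1000 * o$cog[2] +
                                  1e6 * o$cog[3], 0), 6))
  expect_equal(got_cogs, exp_cogs)
})
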