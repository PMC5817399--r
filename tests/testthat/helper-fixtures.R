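# shared fixtures and independent oracles, built in code

# random similarity transform of a shape
transformCopy <- function(shape, rot = runif(1, 0, 2 * pi),
                          scale = runif(1, 0.2, 5),
                          shift = runif(2, -20, 20)) {
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  scale * shape %*% R + matrix(shift, nrow(shape), 2, byrow = TRUE)
}

# independent 2-D hull-area oracle: grDevices::chull boundary + shoelace
shoelaceArea <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nxt <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
}

# independent 3-D hull-volume oracle: Monte-Carlo hit-or-miss, with hull
# membership decided by Caratheodory (a point of conv(P) lies in some
# tetrahedron of 4 points of P) -- no shared code with convexHullVolume()
mcHullVolume3D <- function(pts, n_samples = 1e6, seed = 1) {
  set.seed(seed)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  box <- prod(hi - lo)
  q <- cbind(runif(n_samples, lo[1], hi[1]),
             runif(n_samples, lo[2], hi[2]),
             runif(n_samples, lo[3], hi[3]))
  inside <- rep(FALSE, n_samples)
  for (tet in utils::combn(nrow(pts), 4, simplify = FALSE)) {
    todo <- which(!inside)
    if (!length(todo)) break
    v <- pts[tet, , drop = FALSE]
    A <- t(v[-1, , drop = FALSE]) - v[1, ]
    if (abs(det(A)) < 1e-12) next
    lam <- solve(A, t(q[todo, , drop = FALSE]) - v[1, ])
    ok <- lam[1, ] >= -1e-12 & lam[2, ] >= -1e-12 & lam[3, ] >= -1e-12 &
      colSums(lam) <= 1 + 1e-12
    inside[todo[ok]] <- TRUE
  }
  box * mean(inside)
}

# tiny two-bin scheme for focused simulations
twoBinScheme <- function() {
  timeBinScheme(data.frame(bin = c("older", "younger"),
                           stage = c("StageA", "StageB"),
                           midpoint_ma = c(200, 100)))
}

# minimal valid metadata table for a set of specimen ids
makeMetadata <- function(ids, stage = "Anisian", infraclass = "Chondrostei",
                         environment = "marine", lagerstatten = FALSE) {
  data.frame(specimen_id = ids, species = paste0("sp_", ids),
             genus = "g", family = "f",
             infraclass = infraclass, environment = environment,
             stage = stage, lagerstatten_only = lagerstatten,
             stringsAsFactors = FALSE)
}
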