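# Fixture builders: rasterized shapes as logical masks / NucleusRegion,
# and small seeded images. All generated in code at test time.

diskMask <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  matrix((row(matrix(0, n, n)) - ctr)^2 +
         (col(matrix(0, n, n)) - ctr)^2 <= r^2, n, n)
}

rectMask <- function(h, w, pad = 3L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- TRUE
  m
}

ellipseMask <- function(p, q, angle = 0, pad = 3L) {
  H <- ceiling(max(p, q)) + pad
  n <- 2L * H + 1L
  dr <- row(matrix(0, n, n)) - H - 1L
  dc <- col(matrix(0, n, n)) - H - 1L
  x <- cos(angle) * dc + sin(angle) * dr
  y <- -sin(angle) * dc + cos(angle) * dr
  (x / p)^2 + (y / q)^2 <= 1
}

diskRegion <- function(r, pad = 3L) regionFromMask(diskMask(r, pad))
rectRegion <- function(h, w, pad = 3L) regionFromMask(rectMask(h, w, pad))

# random connected blob: random walk dilation from a center pixel
blobRegion <- function(npix, seed, n = 25L) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  cur <- c(n %/% 2L, n %/% 2L)
  m[cur[1L], cur[2L]] <- TRUE
  while (sum(m) < npix) {
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    cur <- pmin(pmax(cur + step, 2L), n - 1L)
    m[cur[1L], cur[2L]] <- TRUE
  }
  regionFromMask(m)
}

seededImage <- function(nr, nc, seed, lo = 0, hi = 255) {
  set.seed(seed)
  grayImage(matrix(round(runif(nr * nc, lo, hi)), nr, nc))
}
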