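# Differentiable layer primitives for the 3D encoder-decoder. Convolutions run
# in C++ (im2col + GEMM); normalization and activations are vectorized R.
# Every *_fw returns the activation plus the cache its *_bw needs; backward
# passes are exact analytic adjoints (verified against finite differences in
# the test suite).

he_conv <- function(cout, cin, k) {
  fan_in <- cin * k^3
  array(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), dim = c(cout, cin, k, k, k))
}

relu_fw <- function(x) list(y = pmax(x, 0), mask = x > 0)

# Instance normalization: per-channel zero mean / unit variance over the
# spatial voxels of one exam, with learnable scale and shift (C++ kernels).
inorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  r <- .inorm_fw(x, gamma, beta, eps)
  list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd, d = dim(x)))
}

inorm_bw <- function(gy, cache, gamma) {
  if (is.null(dim(gy))) dim(gy) <- cache$d
  .inorm_bw(gy, cache$xhat, cache$istd, gamma)
}

# conv -> instance norm -> ReLU
cbr_fw <- function(x, p, nm, stride = 1L) {
  z <- .conv3d_fw(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]], stride)
  nf <- inorm_fw(z, p[[paste0(nm, ".g")]], p[[paste0(nm, ".bt")]])
  a <- relu_fw(nf$y)
  list(out = a$y, cache = list(x = x, nf = nf$cache, rmask = a$mask))
}

cbr_bw <- function(gy, cache, p, nm, stride = 1L, grads) {
  nb <- inorm_bw(gy * cache$rmask, cache$nf, p[[paste0(nm, ".g")]])
  cb <- .conv3d_bw(cache$x, p[[paste0(nm, ".w")]], nb$gx, stride)
  grads[[paste0(nm, ".w")]] <- cb$gw
  grads[[paste0(nm, ".b")]] <- cb$gb
  grads[[paste0(nm, ".g")]] <- nb$ggamma
  grads[[paste0(nm, ".bt")]] <- nb$gbeta
  list(gx = cb$gx, grads = grads)
}

# Residual block: x + IN(conv(ReLU(IN(conv(x))))) followed by ReLU.
resblock_fw <- function(x, p, nm) {
  b1 <- cbr_fw(x, p, paste0(nm, ".c1"))
  z2 <- .conv3d_fw(b1$out, p[[paste0(nm, ".c2.w")]], p[[paste0(nm, ".c2.b")]], 1L)
  n2 <- inorm_fw(z2, p[[paste0(nm, ".c2.g")]], p[[paste0(nm, ".c2.bt")]])
  s <- x + n2$y
  a <- relu_fw(s)
  list(out = a$y, cache = list(b1 = b1$cache, h = b1$out, n2 = n2$cache, rmask = a$mask))
}

resblock_bw <- function(gy, cache, p, nm, grads) {
  gs <- gy * cache$rmask
  nb <- inorm_bw(gs, cache$n2, p[[paste0(nm, ".c2.g")]])
  cb <- .conv3d_bw(cache$h, p[[paste0(nm, ".c2.w")]], nb$gx, 1L)
  grads[[paste0(nm, ".c2.w")]] <- cb$gw
  grads[[paste0(nm, ".c2.b")]] <- cb$gb
  grads[[paste0(nm, ".c2.g")]] <- nb$ggamma
  grads[[paste0(nm, ".c2.bt")]] <- nb$gbeta
  r1 <- cbr_bw(cb$gx, cache$b1, p, paste0(nm, ".c1"), 1L, grads)
  list(gx = gs + r1$gx, grads = r1$grads)
}
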