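# Internal layer primitives with explicit reverse-mode gradients.
# Volumes are channel-last 4D arrays (nx, ny, nz, C); convolution weights
# are (3, 3, 3, Cin, Cout) so that matrix(W, 27*Cin, Cout) matches the row
# order produced by cpp_im2col.

conv_fwd <- function(x4, W, b, keep = TRUE) {
  din <- as.integer(dim(x4))
  out <- cpp_conv3_fwd(x4, din, W, b)
  list(out = out, x = if (keep) x4 else NULL, din = din)
}

conv_bwd <- function(cache, g4, W) {
  cpp_conv3_bwd(cache$x, cache$din, W, as.integer(dim(W)), g4)
}

gn_fwd <- function(x4, gamma, beta, groups, eps = 1e-5) {
  d <- as.integer(dim(x4))
  r <- cpp_gn_fwd(x4, d, gamma, beta, groups, eps)
  list(out = r$out, xhat = r$xhat, istd = r$istd, groups = groups, d = d)
}

gn_bwd <- function(cache, g4, gamma) {
  r <- cpp_gn_bwd(g4, cache$d, cache$xhat, cache$istd, gamma, cache$groups)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

fc_fwd <- function(x, W, b) as.numeric(W %*% x) + b

# convolution + group norm + ReLU block
block_fwd <- function(x4, P, nm, groups) {
  cv <- conv_fwd(x4, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]])
  gn <- gn_fwd(cv$out, P[[paste0(nm, ".g")]], P[[paste0(nm, ".be")]], groups)
  rl <- relu_fwd(gn$out)
  list(out = rl$out, cv = cv, gn = gn, mask = rl$mask)
}

block_bwd <- function(cache, g4, P, nm, grads) {
  g4 <- g4 * cache$mask
  gb <- gn_bwd(cache$gn, g4, P[[paste0(nm, ".g")]])
  cb <- conv_bwd(cache$cv, gb$dx, P[[paste0(nm, ".W")]])
  grads[[paste0(nm, ".W")]] <- cb$dW
  grads[[paste0(nm, ".b")]] <- cb$db
  grads[[paste0(nm, ".g")]] <- gb$dgamma
  grads[[paste0(nm, ".be")]] <- gb$dbeta
  list(dx = cb$dx, grads = grads)
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
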