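# independent per-face upwind flux enumeration used as the oracle; plain
# loops, one face at a time, no shared code with advect()
brute_force_advect <- function(field, u, v, grid, secs) {
  nr <- grid$nlat; nc <- grid$nlon
  div <- matrix(0, nr, nc)
  export <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (j < nc) { # east face of (i, j)
        uf <- (u[i, j] + u[i, j + 1]) / 2
        fl <- if (uf > 0) uf * secs / grid$dx[i] * field[i, j]
              else uf * secs / grid$dx[i] * field[i, j + 1]
        div[i, j] <- div[i, j] + fl
        div[i, j + 1] <- div[i, j + 1] - fl
      }
      if (i < nr) { # north face of (i, j)
        vf <- (v[i, j] + v[i + 1, j]) / 2
        fl <- if (vf > 0) vf * secs / grid$dy * field[i, j]
              else vf * secs / grid$dy * field[i + 1, j]
        div[i, j] <- div[i, j] + fl
        div[i + 1, j] <- div[i + 1, j] - fl
      }
    }
  }
  for (i in seq_len(nr)) {
    if (u[i, 1] < 0) {
      fl <- -u[i, 1] * secs / grid$dx[i] * field[i, 1]
      div[i, 1] <- div[i, 1] + fl; export <- export + fl
    }
    if (u[i, nc] > 0) {
      fl <- u[i, nc] * secs / grid$dx[i] * field[i, nc]
      div[i, nc] <- div[i, nc] + fl; export <- export + fl
    }
  }
  for (j in seq_len(nc)) {
    if (v[1, j] < 0) {
      fl <- -v[1, j] * secs / grid$dy * field[1, j]
      div[1, j] <- div[1, j] + fl; export <- export + fl
    }
    if (v[nr, j] > 0) {
      fl <- v[nr, j] * secs / grid$dy * field[nr, j]
      div[nr, j] <- div[nr, j] + fl; export <- export + fl
    }
  }
  list(field = field - div, boundary_export = export)
}
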