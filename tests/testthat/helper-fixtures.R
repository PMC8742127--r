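# shared fixtures and independent oracles

# independent single-threaded photon-transport oracle for a homogeneous,
# index-matched box: analytic (voxel-free) geometry, Henyey-Greenstein
# scattering, continuous Beer attenuation, no roulette. Returns the weight
# escaping through each face group. Written independently of the engine:
# free paths are sampled against the box faces directly.
oracleBoxMC <- function(n, mua, mus, g, lx, ly, lz, srcX, srcY, seed) {
  set.seed(seed)
  wTop <- 0; wBottom <- 0; wSide <- 0
  for (i in seq_len(n)) {
    p <- c(srcX, srcY, 0)
    u <- c(0, 0, 1)
    w <- 1
    repeat {
      s <- if (mus > 0) -log(runif(1)) / mus else Inf
      # distance to the box along u
      tb <- Inf; face <- NA_character_
      for (a in 1:3) {
        lim <- c(lx, ly, lz)[a]
        if (u[a] > 1e-12) t <- (lim - p[a]) / u[a]
        else if (u[a] < -1e-12) t <- -p[a] / u[a]
        else next
        if (t < tb) {
          tb <- t
          face <- if (a == 3 && u[3] < 0) "top"
                  else if (a == 3) "bottom" else "side"
        }
      }
      ds <- min(s, tb)
      p <- p + u * ds
      w <- w * exp(-mua * ds)
      if (tb <= s) {
        if (face == "top") wTop <- wTop + w
        else if (face == "bottom") wBottom <- wBottom + w
        else wSide <- wSide + w
        break
      }
      # Henyey-Greenstein deflection
      ct <- if (abs(g) < 1e-6) 2 * runif(1) - 1 else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * runif(1))
        max(-1, min(1, (1 + g^2 - tmp^2) / (2 * g)))
      }
      st <- sqrt(1 - ct^2)
      phi <- 2 * pi * runif(1)
      if (abs(u[3]) > 0.99999) {
        u <- c(st * cos(phi), st * sin(phi), ct * sign(u[3]))
      } else {
        den <- sqrt(1 - u[3]^2)
        u <- c(st * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / den +
                 u[1] * ct,
               st * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / den +
                 u[2] * ct,
               -den * st * cos(phi) + u[3] * ct)
      }
      u <- u / sqrt(sum(u^2))
      if (w < 1e-7) break  # negligible residual weight
    }
  }
  c(top = wTop, bottom = wBottom, side = wSide) / n
}

# homogeneous scattering fixture shared by engine tests
scatterProps <- function(mua = 0.5, mus = 10, g = 0.8, n = 1.0)
  opticalProperties(mua, mus, g, n, name = "slab")

# closed-form OLS via normal equations (oracle for fitKnormRegression)
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# surrogate calibration dataset small enough for fast tests
smallDataset <- function(n = 60, seed = 42, ...)
  generateCalibrationDataset(surrogateConfig(nPropertySets = n, seed = seed,
                                             ...))
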