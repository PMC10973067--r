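# Fixtures built in code: small networks, tube phantoms and masks.

# straight tube network along x
tube_network <- function(radius = 4, len = 40) {
  nodes <- data.frame(id = c("a", "b"), x = c(0, len), y = 16, z = 16,
                      kind = c("inlet", "outlet"), label = c("in", "out"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = "t", from = "a", to = "b", length = len,
                      radius = radius, kind = "vessel",
                      stringsAsFactors = FALSE)
  vesselNetwork(nodes, edges)
}

# trunk with nSide side outlets plus one distal main outlet
trunk_network <- function(nSide = 3, trunkRadius = 1.5, sideRadius = 0.9,
                          seg = 10, sideLen = 8) {
  nodes <- data.frame(id = "in", x = 0, y = 0, z = 0, kind = "inlet",
                      label = "IN", stringsAsFactors = FALSE)
  edges <- NULL
  prev <- "in"
  for (i in seq_len(nSide)) {
    jid <- sprintf("j%d", i)
    nodes <- rbind(nodes, data.frame(id = jid, x = i * seg, y = 0, z = 0,
                                     kind = "junction", label = jid))
    edges <- rbind(edges, data.frame(id = sprintf("t%d", i), from = prev,
                                     to = jid, length = seg,
                                     radius = trunkRadius, kind = "vessel"))
    sid <- sprintf("s%d", i)
    nodes <- rbind(nodes, data.frame(id = sid, x = i * seg, y = sideLen,
                                     z = 0, kind = "outlet", label = sid))
    edges <- rbind(edges, data.frame(id = sprintf("se%d", i), from = jid,
                                     to = sid, length = sideLen,
                                     radius = sideRadius, kind = "vessel"))
    prev <- jid
  }
  nodes <- rbind(nodes, data.frame(id = "out", x = (nSide + 1) * seg, y = 0,
                                   z = 0, kind = "outlet", label = "main.out"))
  edges <- rbind(edges, data.frame(id = "tend", from = prev, to = "out",
                                   length = seg, radius = trunkRadius,
                                   kind = "vessel"))
  vesselNetwork(nodes, edges)
}

# symmetric two-limb loop between the same pair of nodes
loop_network <- function(radius = 1, len = 20) {
  nodes <- data.frame(id = c("in", "a", "b", "out"),
                      x = c(0, 5, 25, 30), y = 0, z = 0,
                      kind = c("inlet", "junction", "junction", "outlet"),
                      label = c("IN", "a", "b", "OUT"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = c("e_in", "limb1", "limb2", "e_out"),
                      from = c("in", "a", "a", "b"),
                      to = c("a", "b", "b", "out"),
                      length = c(5, len + 2, len + 2, 5),
                      radius = radius, kind = "vessel",
                      stringsAsFactors = FALSE)
  vesselNetwork(nodes, edges)
}

# digitized ball mask (radius in voxels)
ball_mask <- function(r = 8, n = 32, spacing = 1) {
  cx <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  m <- array(with(g, sqrt((i - cx)^2 + (j - cx)^2 + (k - cx)^2)) <= r,
             c(n, n, n))
  new("SegmentationMask", mask = m, spacing = spacing, origin = c(0, 0, 0),
      seeds = matrix(as.integer(round(c(cx, cx, cx))), 1))
}

# partial-volume tube volume along the z axis, radius in voxels
tube_volume <- function(radius = 4, n = 40, L = 30, spacing = 1,
                        lumen = 100, background = 0, margin = 6) {
  net <- vesselNetwork(
    data.frame(id = c("a", "b"),
               x = (n + 1) / 2 * spacing, y = (n + 1) / 2 * spacing,
               z = c(2 * spacing, (L - 1) * spacing),
               kind = c("inlet", "outlet"), label = c("in", "out"),
               stringsAsFactors = FALSE),
    data.frame(id = "t", from = "a", to = "b", length = (L - 3) * spacing,
               radius = radius * spacing, kind = "vessel",
               stringsAsFactors = FALSE))
  rasterizeNetwork(net, spacing = spacing, lumenIntensity = lumen,
                   backgroundIntensity = background, noiseSd = 0, seed = 1,
                   margin = margin)
}

# vectorized independent fixed-point oracle for banded region growing
grow_oracle <- function(vol, seeds, tol) {
  d <- dim(vol)
  shift <- function(a, di, dj, dk) {
    out <- array(FALSE, d)
    si <- max(1, 1 + di):min(d[1], d[1] + di)
    sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
    sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
    out[si, sj, sk] <- a[si - di, sj - dj, sk - dk]
    out
  }
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  total <- array(FALSE, d)
  for (s in seq_len(nrow(seeds))) {
    iref <- vol[seeds[s, 1], seeds[s, 2], seeds[s, 3]]
    band <- vol >= iref - tol * abs(iref) & vol <= iref + tol * abs(iref)
    adm <- array(FALSE, d)
    adm[seeds[s, 1], seeds[s, 2], seeds[s, 3]] <- TRUE
    adm <- adm & band
    repeat {
      grown <- adm
      for (o in seq_len(nrow(offs)))
        grown <- grown | shift(adm, offs$di[o], offs$dj[o], offs$dk[o])
      grown <- grown & band
      if (identical(grown, adm)) break
      adm <- grown
    }
    adm[seeds[s, 1], seeds[s, 2], seeds[s, 3]] <- TRUE  # seed always included
    total <- total | adm
  }
  total
}

# independent Gaussian-derivative Hessian at one voxel (no reflection:
# keep the voxel away from the boundary)
hessian_oracle <- function(vol, sigma, at) {
  rad <- max(1, ceiling(4 * sigma))
  i <- -rad:rad
  g <- exp(-0.5 * i^2 / sigma^2); g <- g / sum(g)
  g1 <- i * g / sum(i^2 * g)
  k2 <- (i^2 / sigma^4 - 1 / sigma^2) * g
  k2 <- k2 - mean(k2)
  k2 <- k2 / sum(0.5 * i^2 * k2)
  kern <- list(g, g1, k2)
  sub <- vol[at[1] + i, at[2] + i, at[3] + i]
  comp <- function(ox, oy, oz) {
    k3 <- outer(outer(kern[[ox + 1]], kern[[oy + 1]]), kern[[oz + 1]])
    sum(k3 * sub)
  }
  H <- matrix(0, 3, 3)
  H[1, 1] <- comp(2, 0, 0); H[2, 2] <- comp(0, 2, 0); H[3, 3] <- comp(0, 0, 2)
  H[1, 2] <- H[2, 1] <- comp(1, 1, 0)
  H[1, 3] <- H[3, 1] <- comp(1, 0, 1)
  H[2, 3] <- H[3, 2] <- comp(0, 1, 1)
  sigma^2 * H
}

frangi_oracle <- function(H, alpha = 0.5, beta = 0.5, c = 2) {
  ev <- eigen(H, symmetric = TRUE)$values
  ev <- ev[order(abs(ev))]
  if (ev[2] > 0 || ev[3] > 0) return(0)
  RA <- abs(ev[2]) / abs(ev[3])
  RB <- abs(ev[1]) / sqrt(abs(ev[2] * ev[3]))
  S2 <- sum(ev^2)
  (1 - exp(-RA^2 / (2 * alpha^2))) * exp(-RB^2 / (2 * beta^2)) *
    (1 - exp(-S2 / (2 * c^2)))
}
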