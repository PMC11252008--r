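## Marching cubes case table, derived from first principles at load time:
## on every cube face a marching-squares pass yields iso-segments (the
## ambiguous two-diagonal case is resolved by always separating the inside
## corners, a rule both neighbouring cubes apply identically, which makes the
## global surface watertight); segments chain into closed loops that are
## fan-triangulated. Vertices live on cube-edge midpoints (binary field,
## iso-level 0.5).

## cube corners, 0-based bit i of the configuration; coordinates (z, y, x)
.mc_corners <- matrix(c(
  0,0,0, 0,0,1, 0,1,0, 0,1,1,
  1,0,0, 1,0,1, 1,1,0, 1,1,1), ncol = 3, byrow = TRUE)

## cube edges as 0-based corner pairs (all axis-aligned)
.mc_edges <- matrix(c(
  0,1, 0,2, 1,3, 2,3, 4,5, 4,6, 5,7, 6,7, 0,4, 1,5, 2,6, 3,7),
  ncol = 2, byrow = TRUE)

## faces as 0-based corner quadruples in cyclic order
.mc_faces <- matrix(c(
  0,1,3,2, 4,5,7,6, 0,1,5,4, 2,3,7,6, 0,2,6,4, 1,3,7,5),
  ncol = 4, byrow = TRUE)

.mc_env <- new.env(parent = emptyenv())

.mc_edge_id <- local({
  key <- function(a, b) paste(min(a, b), max(a, b))
  ids <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(.mc_edges)))
    assign(key(.mc_edges[e, 1], .mc_edges[e, 2]), e - 1L, envir = ids)
  function(a, b) get(paste(min(a, b), max(a, b)), envir = ids)
})

.mc_edge_mid <- function(e) {
  (.mc_corners[.mc_edges[e + 1L, 1] + 1L, ] +
   .mc_corners[.mc_edges[e + 1L, 2] + 1L, ]) / 2
}

## marching squares on one face -> list of segments (pairs of 0-based edges)
.mc_face_segments <- function(face, inside) {
  ins <- inside[face + 1L]
  n <- sum(ins)
  if (n == 0L || n == 4L) return(list())
  bip <- list()
  for (k in 1:4) {
    a <- face[k]; b <- face[k %% 4 + 1]
    if (inside[a + 1L] != inside[b + 1L])
      bip[[length(bip) + 1L]] <- .mc_edge_id(a, b)
  }
  if (length(bip) == 2L) return(list(c(bip[[1]], bip[[2]])))
  ## ambiguous face: two diagonal inside corners -> cut off each one
  segs <- list()
  for (k in 1:4) {
    c0 <- face[k]
    if (inside[c0 + 1L]) {
      prv <- face[(k - 2) %% 4 + 1]; nxt <- face[k %% 4 + 1]
      segs[[length(segs) + 1L]] <- c(.mc_edge_id(prv, c0), .mc_edge_id(c0, nxt))
    }
  }
  segs
}

.mc_build_table <- function() {
  table <- vector("list", 256L)
  for (cfg in 0:255) {
    inside <- bitwAnd(bitwShiftR(cfg, 0:7), 1L) == 1L
    segs <- list()
    for (f in seq_len(nrow(.mc_faces)))
      segs <- c(segs, .mc_face_segments(.mc_faces[f, ], inside))
    if (!length(segs)) { table[[cfg + 1L]] <- integer(); next }
    ## chain segments into closed loops
    segmat <- do.call(rbind, segs)
    used <- rep(FALSE, nrow(segmat))
    loops <- list()
    repeat {
      s0 <- which(!used)[1]
      if (is.na(s0)) break
      loop <- c(segmat[s0, 1], segmat[s0, 2])
      used[s0] <- TRUE
      repeat {
        cur <- loop[length(loop)]
        if (cur == loop[1]) { loop <- loop[-length(loop)]; break }
        nxt <- which(!used & (segmat[, 1] == cur | segmat[, 2] == cur))[1]
        if (is.na(nxt)) break
        used[nxt] <- TRUE
        loop <- c(loop, if (segmat[nxt, 1] == cur) segmat[nxt, 2]
                        else segmat[nxt, 1])
      }
      loops[[length(loops) + 1L]] <- loop
    }
    cin <- colMeans(.mc_corners[which(inside), , drop = FALSE])
    tris <- integer()
    for (loop in loops) {
      if (length(loop) < 3L) next
      for (k in 2:(length(loop) - 1L)) {
        t <- c(loop[1], loop[k], loop[k + 1])
        a <- .mc_edge_mid(t[1]); b <- .mc_edge_mid(t[2]); cc <- .mc_edge_mid(t[3])
        nrm <- c(
          (b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
          (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
          (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
        ctr <- (a + b + cc) / 3
        if (sum(nrm * (ctr - cin)) < 0) t <- t[c(1, 3, 2)]
        tris <- c(tris, t)
      }
    }
    table[[cfg + 1L]] <- as.integer(tris)
  }
  table
}

.mc_table <- function() {
  if (is.null(.mc_env$table)) .mc_env$table <- .mc_build_table()
  .mc_env$table
}
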