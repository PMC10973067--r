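## Internal helpers.

# Evaluate expr with a temporarily seeded RNG, restoring global state after,
# so generators are pure functions of (arguments, seed).
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# any unit vector perpendicular to d
.perp <- function(d) {
  d <- .normalize(d)
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  .normalize(pracma_cross(ref, d))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.edge_segments <- function(network) {
  nd <- network@nodes
  ed <- network@edges
  pos <- as.matrix(nd[, c("x", "y", "z")])
  rownames(pos) <- nd$id
  cbind(pos[as.character(ed$from), , drop = FALSE],
        pos[as.character(ed$to), , drop = FALSE],
        ed$radius)
}

# igraph view of a network (undirected, vertex names = node ids)
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(network@edges$from),
               to = as.character(network@edges$to),
               id = as.character(network@edges$id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network@nodes$id)))
}

# reclassify non-boundary node kinds from degree (junction >= 3, else internal)
.refresh_kinds <- function(nodes, edges) {
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  fixed <- nodes$kind %in% c("inlet", "outlet", "aneurysm_sac")
  nodes$kind[!fixed] <- ifelse(deg[!fixed] >= 3, "junction", "internal")
  nodes
}

.dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
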