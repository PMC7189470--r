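#' Compensate an event table for fluorescence spillover
#'
#' Multiplies each event row by the inverse spillover matrix (classical
#' linear unmixing).  The identity matrix is a no-op.
#'
#' @param events data.frame of channel intensities (columns must match the
#'   spillover ordering).
#' @param spillover square spillover matrix; `spillover[i, j]` is the
#'   fraction of channel i signal detected in channel j.
#' @return compensated event data.frame.
#' @export
compensate <- function(events, spillover) {
  stopifnot(is.matrix(spillover), nrow(spillover) == ncol(spillover))
  chans <- colnames(spillover) %||% colnames(events)
  if (!all(chans %in% colnames(events)))
    stop("spillover channels missing from event table")
  if (nrow(spillover) != length(chans))
    stop("spillover dimension does not match channel count")
  rc <- rcond(spillover)
  if (!is.finite(rc) || rc < 1e-12) stop("spillover matrix is singular")
  out <- events
  out[chans] <- as.data.frame(as.matrix(events[chans]) %*% solve(spillover))
  out
}

#' A node of a sequential gating tree
#'
#' Membership requires all per-channel conditions: channels with sign
#' `+1` must have intensity at or above the threshold, channels with sign
#' `-1` must be strictly below (events exactly at a threshold fall on the
#' positive side).
#'
#' @param name node name.
#' @param parent parent node name, or `"root"` for all events.
#' @param thresholds named numeric thresholds (names are channels).
#' @param signs named vector of `+1`/`-1` matching `thresholds`.
#' @return a `gate_node` list.
#' @export
gate_node <- function(name, parent, thresholds, signs) {
  stopifnot(is.character(name), is.character(parent),
            length(thresholds) == length(signs),
            setequal(names(thresholds), names(signs)),
            all(signs %in% c(-1, 1)))
  structure(list(name = name, parent = parent,
                 thresholds = thresholds, signs = signs[names(thresholds)]),
            class = "gate_node")
}

#' The default murine myeloid gating tree
#'
#' live (PI-) -> CD45+ -> macrophage (CD11b+ F4/80+), DC (CD11c+ MHCII+
#' F4/80-), G-MDSC (CD11b+ Ly6G+), M-MDSC (CD11b+ Ly6C-high Ly6G-).
#' Gate geometry is fully configurable: supply any list of [gate_node()]s
#' (or a YAML file via [read_gate_tree()]) to use another tree.
#'
#' @param thresholds named per-channel scalar thresholds, e.g. from
#'   [auto_gate_thresholds()].
#' @return list of `gate_node`s.
#' @export
default_gate_tree <- function(thresholds) {
  thr <- function(...) thresholds[c(...)]
  list(
    gate_node("live", "root", thr("PI"), c(PI = -1)),
    gate_node("cd45", "live", thr("CD45"), c(CD45 = 1)),
    gate_node("macrophage", "cd45", thr("CD11b", "F480"),
              c(CD11b = 1, F480 = 1)),
    gate_node("dc", "cd45", thr("CD11c", "MHCII", "F480"),
              c(CD11c = 1, MHCII = 1, F480 = -1)),
    gate_node("gmdsc", "cd45", thr("CD11b", "Ly6G"),
              c(CD11b = 1, Ly6G = 1)),
    gate_node("mmdsc", "cd45", thr("CD11b", "Ly6C", "Ly6G"),
              c(CD11b = 1, Ly6C = 1, Ly6G = -1)))
}

## order nodes so parents precede children; errors on cycles/missing parents
sort_gate_tree <- function(tree) {
  names(tree) <- vapply(tree, `[[`, "", "name")
  placed <- character(0); out <- list()
  remaining <- tree
  while (length(remaining)) {
    ready <- vapply(remaining, function(nd)
      nd$parent == "root" || nd$parent %in% placed, logical(1))
    if (!any(ready)) stop("gate tree is cyclic or has missing parents: ",
                          paste(names(remaining), collapse = ", "))
    out <- c(out, remaining[ready])
    placed <- c(placed, names(remaining)[ready])
    remaining <- remaining[!ready]
  }
  out
}

#' Apply a sequential gating tree to an event table
#'
#' Each gate is evaluated only within its parent population, so an event
#' can never enter a gate whose ancestor excluded it.  Fractions are
#' reported against the parent gate and against the CD45+ gate (the tumor
#' immune population) for gates at or below a node named `cd45`.
#'
#' @param events (compensated) event data.frame.
#' @param tree list of [gate_node()]s.
#' @return data.frame with `name`, `count`, `pct_of_parent`, `pct_of_cd45`
#'   and `flag` (`"empty_parent"` when a fraction is undefined).
#' @export
apply_gate_tree <- function(events, tree) {
  tree <- sort_gate_tree(tree)
  for (nd in tree)
    if (!all(names(nd$thresholds) %in% colnames(events)))
      stop("gate '", nd$name, "' references channels missing from the table: ",
           paste(setdiff(names(nd$thresholds), colnames(events)),
                 collapse = ", "))
  n <- nrow(events)
  member <- list(root = rep(TRUE, n))
  res <- data.frame(name = character(0), count = integer(0),
                    pct_of_parent = numeric(0), pct_of_cd45 = numeric(0),
                    flag = character(0), stringsAsFactors = FALSE)
  below_cd45 <- function(nm) {
    while (nm != "root") {
      if (nm == "cd45") return(TRUE)
      nm <- tree[[nm]]$parent
    }
    FALSE
  }
  for (nd in tree) {
    ok <- member[[nd$parent]]
    for (ch in names(nd$thresholds)) {
      v <- events[[ch]]
      ok <- ok & if (nd$signs[ch] > 0) v >= nd$thresholds[ch]
                 else v < nd$thresholds[ch]
    }
    member[[nd$name]] <- ok
    np <- sum(member[[nd$parent]])
    cnt <- sum(ok)
    flag <- ""
    pp <- if (np > 0) 100 * cnt / np else { flag <- "empty_parent"; NA_real_ }
    pc <- NA_real_
    if (below_cd45(nd$name)) {
      ncd <- sum(member[["cd45"]])
      pc <- if (ncd > 0) 100 * cnt / ncd else { flag <- "empty_parent"; NA_real_ }
    } else if (nd$name == "cd45") pc <- 100
    res <- rbind(res, data.frame(name = nd$name, count = cnt,
                                 pct_of_parent = pp, pct_of_cd45 = pc,
                                 flag = flag, stringsAsFactors = FALSE))
  }
  attr(res, "membership") <- member
  res
}

#' CD38/CD206 quadrant phenotyping of gated macrophages
#'
#' M0 = CD38-/CD206-, M1 = CD38+/CD206-, M2 = CD38-/CD206+, co =
#' CD38+/CD206+.  Events exactly at a threshold count as positive; the
#' four quadrant counts always sum exactly to the macrophage count.
#'
#' @param macrophage_events events already inside the macrophage gate.
#' @param cd38_thr,cd206_thr scalar thresholds.
#' @return data.frame (`name`, `count`, `pct_of_parent`).
#' @export
macrophage_quadrants <- function(macrophage_events, cd38_thr, cd206_thr) {
  cd38 <- macrophage_events$CD38 >= cd38_thr
  cd206 <- macrophage_events$CD206 >= cd206_thr
  n <- nrow(macrophage_events)
  counts <- c(M0 = sum(!cd38 & !cd206), M1 = sum(cd38 & !cd206),
              M2 = sum(!cd38 & cd206), co = sum(cd38 & cd206))
  stopifnot(sum(counts) == n)
  data.frame(name = names(counts), count = as.integer(counts),
             pct_of_parent = if (n > 0) 100 * counts / n else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Live-cell fraction from the PI channel
#'
#' @param events event data.frame with a `PI` column.
#' @param pi_thr PI threshold; events strictly below it are live.
#' @return percent of live events.
#' @export
viability_fraction <- function(events, pi_thr) {
  if (nrow(events) == 0) stop("empty event table: viability undefined")
  if (!"PI" %in% colnames(events)) stop("PI channel missing")
  100 * mean(events$PI < pi_thr)
}

#' Place a threshold at the valley of a bimodal channel
#'
#' Intensities are asinh-transformed (default cofactor 150), split by a
#' deterministic 2-means step (centres initialized at the data extremes,
#' so a minority mode as small as a few percent is still found), and the
#' threshold is placed at the kernel-density minimum between the two
#' cluster centres.  Falls back to the midpoint of the centres when the
#' density has no interior minimum.
#'
#' @param x channel intensities.
#' @param cofactor asinh cofactor.
#' @return threshold on the original intensity scale.
#' @export
valley_threshold <- function(x, cofactor = 150) {
  t <- asinh(x / cofactor)
  if (diff(range(t)) < 1e-9) return(sinh(mean(t)) * cofactor)
  km <- suppressWarnings(
    kmeans(t, centers = matrix(range(t), 2, 1), iter.max = 100))
  c1 <- min(km$centers); c2 <- max(km$centers)
  d <- density(t, n = 512)
  sel <- d$x > c1 & d$x < c2
  thr_t <- if (any(sel)) d$x[sel][which.min(d$y[sel])] else (c1 + c2) / 2
  sinh(thr_t) * cofactor
}

#' Automatic per-channel gate thresholds
#'
#' @param events event data.frame.
#' @param channels channels to threshold (default: the full panel).
#' @param max_events cap on events used per channel (the leading rows;
#'   events are exchangeable, and a few thousand suffice to place a
#'   valley).
#' @inheritParams valley_threshold
#' @return named numeric thresholds.
#' @export
auto_gate_thresholds <- function(events, channels = intersect(FLOW_CHANNELS,
                                                              colnames(events)),
                                 cofactor = 150, max_events = 5000L) {
  n <- min(nrow(events), max_events)
  vapply(setNames(channels, channels),
         function(ch) valley_threshold(events[[ch]][seq_len(n)], cofactor),
         numeric(1))
}

#' Read / write a gating tree as YAML
#'
#' @param path YAML file. Each entry has `name`, `parent`, and a
#'   `channels` map of `channel: {threshold, sign}`.
#' @return list of [gate_node()]s.
#' @export
read_gate_tree <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(nd) {
    thr <- vapply(nd$channels, function(c) as.numeric(c$threshold), numeric(1))
    sg <- vapply(nd$channels, function(c) as.numeric(c$sign), numeric(1))
    gate_node(nd$name, nd$parent, thr, sg)
  })
}

#' @rdname read_gate_tree
#' @param tree list of [gate_node()]s to serialize.
#' @export
write_gate_tree <- function(tree, path) {
  out <- lapply(tree, function(nd) {
    chans <- lapply(names(nd$thresholds), function(ch)
      list(threshold = unname(nd$thresholds[ch]), sign = unname(nd$signs[ch])))
    names(chans) <- names(nd$thresholds)
    list(name = nd$name, parent = nd$parent, channels = chans)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
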