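# Admixture-graph data model: construction, minimal text format, root-to-leaf
# path weights and the linear additive-drift expectation
#   E[f2(A,B)] = sum_e (w_A(e) - w_B(e))^2 c_e
# where w_X(e) is the probability mass of root-to-X paths traversing edge e
# (products of alpha/(1-alpha) at admixture nodes).

#' Construct an AdmixtureGraph
#'
#' @param drift_edges data.frame with columns from, to and optionally length
#'   (NA = free parameter). These are ordinary drift edges; edges into
#'   admixture nodes are created from \code{admix} and carry no drift.
#' @param admix optional data.frame with columns node, parent1, parent2,
#'   alpha (the mixing weight of parent1; NA = free).
#' @return an \linkS4class{AdmixtureGraph}. Leaves are nodes without
#'   outgoing edges; the root is the unique node without parents.
#' @export
admixtureGraph <- function(drift_edges, admix = NULL) {
  de <- as.data.frame(drift_edges, stringsAsFactors = FALSE)
  if (is.null(de$length)) de$length <- NA_real_
  de$type <- "drift"
  if (is.null(admix))
    admix <- data.frame(node = character(), parent1 = character(),
                        parent2 = character(), alpha = numeric())
  admix <- as.data.frame(admix, stringsAsFactors = FALSE)
  if (nrow(admix)) {
    me <- data.frame(from = c(admix$parent1, admix$parent2),
                     to = c(admix$node, admix$node),
                     length = 0, type = "mix", stringsAsFactors = FALSE)
    edges <- rbind(de[, c("from", "to", "length", "type")], me)
  } else edges <- de[, c("from", "to", "length", "type")]
  nodes <- union(edges$from, edges$to)
  leaves <- setdiff(nodes, edges$from)
  root <- setdiff(nodes, edges$to)
  if (length(root) != 1L) stop("graph must have exactly one root")
  new("AdmixtureGraph", edges = edges, admix = admix,
      root = root, leaves = sort(leaves))
}

#' @describeIn admixtureGraph leaf populations
#' @param graph an AdmixtureGraph
#' @export
graphLeaves <- function(graph) graph@leaves

#' Set or replace graph parameters
#'
#' @param graph an \linkS4class{AdmixtureGraph}
#' @param lengths named numeric, names "from->to", drift lengths.
#' @param alphas named numeric, names = admixture node names.
#' @return the updated graph.
#' @export
setGraphParams <- function(graph, lengths = NULL, alphas = NULL) {
  if (!is.null(lengths)) {
    key <- paste0(graph@edges$from, "->", graph@edges$to)
    hit <- match(names(lengths), key)
    if (anyNA(hit)) stop("unknown edge(s): ",
                         paste(names(lengths)[is.na(hit)], collapse = ", "))
    graph@edges$length[hit] <- unname(lengths)
  }
  if (!is.null(alphas)) {
    hit <- match(names(alphas), graph@admix$node)
    if (anyNA(hit)) stop("unknown admixture node(s)")
    graph@admix$alpha[hit] <- unname(alphas)
  }
  validObject(graph)
  graph
}

# edge key helper
.edgeKeys <- function(graph) paste0(graph@edges$from, "->", graph@edges$to)

# Per-leaf path-weight matrix over edges: entry [e, leaf] = w_leaf(e).
# alphas: named vector over admixture nodes (overrides stored values).
graphPathWeights <- function(graph, alphas = NULL) {
  e <- graph@edges
  a <- setNames(graph@admix$alpha, graph@admix$node)
  if (!is.null(alphas)) a[names(alphas)] <- alphas
  if (anyNA(a)) stop("unset admixture proportion(s)")
  ord <- topoSortNodes(e)
  leaves <- graph@leaves
  nodes <- ord
  U <- matrix(0, length(nodes), length(leaves), dimnames = list(nodes, leaves))
  U[cbind(leaves, leaves)] <- 1
  W <- matrix(0, nrow(e), length(leaves),
              dimnames = list(.edgeKeys(graph), leaves))
  inmix <- e$type == "mix"
  # walk from leaves to root
  for (v in rev(ord)) {
    idx <- which(e$to == v)
    if (!length(idx)) next
    uv <- U[v, ]
    if (length(idx) == 2L) {  # admixture node
      arow <- match(v, graph@admix$node)
      p1 <- graph@admix$parent1[arow]
      w1 <- a[v]
      for (i in idx) {
        wt <- if (e$from[i] == p1) w1 else 1 - w1
        W[i, ] <- wt * uv
        U[e$from[i], ] <- U[e$from[i], ] + wt * uv
      }
    } else {
      W[idx, ] <- uv
      U[e$from[idx], ] <- U[e$from[idx], ] + uv
    }
  }
  W
}

# Design matrix mapping drift-edge lengths to expected f2 of leaf pairs.
# pairs: 2-column character matrix of leaf pairs. Columns = drift edges.
graphF2Design <- function(graph, pairs, alphas = NULL, weights = NULL) {
  W <- if (is.null(weights)) graphPathWeights(graph, alphas) else weights
  drift <- which(graph@edges$type == "drift")
  D <- matrix(0, nrow(pairs), length(drift),
              dimnames = list(paste(pairs[, 1L], pairs[, 2L], sep = "|"),
                              rownames(W)[drift]))
  for (k in seq_len(nrow(pairs))) {
    dw <- W[drift, pairs[k, 1L]] - W[drift, pairs[k, 2L]]
    D[k, ] <- dw * dw
  }
  D
}

#' Expected f2 matrix under the additive drift model
#'
#' @param graph an \linkS4class{AdmixtureGraph} with all drift lengths and
#'   mixing proportions set.
#' @return symmetric leaf-by-leaf matrix of expected f2 values.
#' @export
expectedF2Matrix <- function(graph) {
  if (anyNA(graph@edges$length)) stop("unset drift length(s)")
  leaves <- graph@leaves
  pairs <- t(combn(leaves, 2L))
  D <- graphF2Design(graph, pairs)
  v <- D %*% graph@edges$length[graph@edges$type == "drift"]
  M <- matrix(0, length(leaves), length(leaves), dimnames = list(leaves, leaves))
  M[cbind(pairs[, 1L], pairs[, 2L])] <- v
  M[cbind(pairs[, 2L], pairs[, 1L])] <- v
  M
}

#' Read / write the minimal admixture-graph text format
#'
#' Drift edges are written one per line as \code{A -> B [length]}; admixture
#' nodes as \code{M = 0.4 P1 + 0.6 P2} (weights may be \code{NA} while
#' unset). Comments start with \code{#}.
#'
#' @param path file path.
#' @return \code{readGraph}: an \linkS4class{AdmixtureGraph}.
#' @export
readGraph <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_adm <- grepl("=", lines, fixed = TRUE)
  adm <- NULL
  if (any(is_adm)) {
    parts <- regmatches(lines[is_adm],
      regexec("^(\\S+)\\s*=\\s*(\\S+)\\s+(\\S+)\\s*\\+\\s*(\\S+)\\s+(\\S+)$",
              lines[is_adm]))
    adm <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) != 6L) stop("malformed admixture line")
      data.frame(node = p[2L], parent1 = p[4L], parent2 = p[6L],
                 alpha = suppressWarnings(as.numeric(p[3L])))
    }))
  }
  ep <- strsplit(lines[!is_adm], "\\s*->\\s*|\\s+")
  de <- do.call(rbind, lapply(ep, function(p) {
    if (length(p) < 2L) stop("malformed edge line")
    data.frame(from = p[1L], to = p[2L],
               length = if (length(p) >= 3L)
                 suppressWarnings(as.numeric(p[3L])) else NA_real_)
  }))
  admixtureGraph(de, adm)
}

#' @rdname readGraph
#' @param graph an \linkS4class{AdmixtureGraph}
#' @export
writeGraph <- function(graph, path) {
  de <- graph@edges[graph@edges$type == "drift", ]
  el <- ifelse(is.na(de$length), "", paste0(" ", format(de$length, trim = TRUE)))
  lines <- paste0(de$from, " -> ", de$to, el)
  if (nrow(graph@admix)) {
    a <- graph@admix
    lines <- c(lines, sprintf("%s = %s %s + %s %s", a$node,
                              format(a$alpha), a$parent1,
                              format(1 - a$alpha), a$parent2))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# The three competing 7-population topologies for the Muturu introgression
# question. Leaves: AfricanBuffalo, Sahiwal, ArmenianAurochs, BritishAurochs,
# MoroccanAurochs, IranBronzeAge, Muturu. All three share the backbone in
# which Sahiwal carries a taurine pulse and the Moroccan aurochs carries a
# pulse from a basal ("deep") taurine branch; B-2 adds a Moroccan-related
# and B-3 a deep-taurine-related gene flow into Muturu.
# ---------------------------------------------------------------------------

.backboneEdges <- function() {
  data.frame(from = c("root", "root", "CATTLE", "CATTLE", "SAHADM",
                      "TAUR", "TAUR", "M60", "M60", "M36", "M36",
                      "M24", "M24", "M15", "M15"),
             to = c("AfricanBuffalo", "CATTLE", "IND", "TAUR", "Sahiwal",
                    "DEEPT", "M60", "BritishAurochs", "M36", "ArmenianAurochs",
                    "M24", "MORPRE", "M15", "SAHDON", "M9"),
             stringsAsFactors = FALSE)
}

# generation counts of the printed split/pulse times (6-yr generations)
.segGens <- function(buffalo_split = c("300kya", "3Mya")) {
  buffalo_split <- match.arg(buffalo_split)
  c(buf = if (buffalo_split == "300kya") round(3e5 / 6) else round(3e6 / 6),
    ind_taur = round(180000 / 6), deep = round(60000 / 6),
    brit = round(36000 / 6), arm = round(24000 / 6), mor = round(15000 / 6),
    mor_pulse = round(12000 / 6), sahdon = round(9000 / 6),
    mut = round(6000 / 6), b2split = round(3600 / 6),
    b3split = round(30000 / 6), pulse = round(3000 / 6),
    sah_pulse = round(6000 / 6))
}

.truthLengths <- function(topology, buffalo_split, Ne = 10000) {
  g <- .segGens(buffalo_split)
  d <- function(gens) unname(gens) / (2 * Ne)
  base <- c("root->AfricanBuffalo" = d(g["buf"]),
            "root->CATTLE" = d(g["buf"] - g["ind_taur"]),
            "CATTLE->IND" = d(g["ind_taur"] - g["sah_pulse"]),
            "SAHADM->Sahiwal" = d(g["sah_pulse"]),
            "CATTLE->TAUR" = d(g["ind_taur"] - g["deep"]),
            "TAUR->M60" = d(g["deep"] - g["brit"]),
            "M60->BritishAurochs" = d(g["brit"]),
            "M60->M36" = d(g["brit"] - g["arm"]),
            "M36->ArmenianAurochs" = d(g["arm"]),
            "M36->M24" = d(g["arm"] - g["mor"]),
            "M24->MORPRE" = d(g["mor"] - g["mor_pulse"]),
            "M24->M15" = d(g["mor"] - g["sahdon"]),
            "M15->SAHDON" = d(g["sahdon"] - g["sah_pulse"]),
            "M15->M9" = d(g["sahdon"] - g["mut"]),
            "M9->IranBronzeAge" = d(g["mut"]))
  extra <- switch(topology,
    "B-1" = c("TAUR->DEEPT" = d(g["deep"] - g["mor_pulse"]),
              "MORADM->MoroccanAurochs" = d(g["mor_pulse"]),
              "M9->Muturu" = d(g["mut"])),
    "B-2" = c("TAUR->DEEPT" = d(g["deep"] - g["mor_pulse"]),
              "MORADM->MORMID" = d(g["mor_pulse"] - g["b2split"]),
              "MORMID->MoroccanAurochs" = d(g["b2split"]),
              "MORMID->MUTDON" = d(g["b2split"] - g["pulse"]),
              "M9->MUTPRE" = d(g["mut"] - g["pulse"]),
              "MUTADM->Muturu" = d(g["pulse"])),
    "B-3" = c("TAUR->DEEPT" = d(g["deep"] - g["b3split"]),
              "DEEPT->DEEPA" = d(g["b3split"] - g["mor_pulse"]),
              "DEEPT->DEEPB" = d(g["b3split"] - g["pulse"]),
              "MORADM->MoroccanAurochs" = d(g["mor_pulse"]),
              "M9->MUTPRE" = d(g["mut"] - g["pulse"]),
              "MUTADM->Muturu" = d(g["pulse"])))
  c(base, extra)
}

#' The competing Muturu admixture-graph topologies
#'
#' Builds the three 7-leaf topologies compared in the robustness experiment:
#' B-1 (no gene flow into Muturu; two backbone admixture events: a taurine
#' pulse into Sahiwal and a deep-taurine pulse into the Moroccan aurochs),
#' B-2 (additional Moroccan-aurochs-related gene flow into Muturu) and B-3
#' (additional deep-taurine gene flow into Muturu).
#'
#' @param topology "B-1", "B-2" or "B-3".
#' @param with_truth fill drift lengths and mixing proportions with the
#'   generating demography's values (times/2Ne; pulse proportions 20/40/20%)
#'   instead of leaving them free.
#' @param buffalo_split "300kya" or "3Mya" (affects truth lengths only).
#' @return an \linkS4class{AdmixtureGraph}.
#' @export
muturuGraph <- function(topology = c("B-1", "B-2", "B-3"), with_truth = FALSE,
                        buffalo_split = c("300kya", "3Mya")) {
  topology <- match.arg(topology)
  buffalo_split <- match.arg(buffalo_split)
  de <- .backboneEdges()
  admix <- data.frame(node = c("SAHADM", "MORADM"),
                      parent1 = c("IND", "MORPRE"),
                      parent2 = c("SAHDON", "DEEPT"),
                      alpha = NA_real_, stringsAsFactors = FALSE)
  if (topology == "B-1") {
    de <- rbind(de, data.frame(from = c("MORADM", "M9", "M9"),
                               to = c("MoroccanAurochs", "Muturu",
                                      "IranBronzeAge")))
  } else if (topology == "B-2") {
    de <- rbind(de, data.frame(
      from = c("MORADM", "MORMID", "MORMID", "M9", "M9", "MUTADM"),
      to = c("MORMID", "MoroccanAurochs", "MUTDON", "MUTPRE",
             "IranBronzeAge", "Muturu")))
    admix <- rbind(admix, data.frame(node = "MUTADM", parent1 = "MUTPRE",
                                     parent2 = "MUTDON", alpha = NA_real_))
  } else {
    de <- rbind(de, data.frame(
      from = c("DEEPT", "DEEPT", "MORADM", "M9", "M9", "MUTADM"),
      to = c("DEEPA", "DEEPB", "MoroccanAurochs", "MUTPRE",
             "IranBronzeAge", "Muturu")))
    admix$parent2[admix$node == "MORADM"] <- "DEEPA"
    admix <- rbind(admix, data.frame(node = "MUTADM", parent1 = "MUTPRE",
                                     parent2 = "DEEPB", alpha = NA_real_))
  }
  g <- admixtureGraph(de, admix)
  if (with_truth) {
    alphas <- c(SAHADM = 0.8, MORADM = 0.6)
    if (topology == "B-2") alphas <- c(alphas, MUTADM = 0.6)
    if (topology == "B-3") alphas <- c(alphas, MUTADM = 0.8)
    g <- setGraphParams(g, lengths = .truthLengths(topology, buffalo_split),
                        alphas = alphas)
  }
  g
}
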