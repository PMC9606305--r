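#' Parse a GFA1 assembly graph
#'
#' Reads S (segment) and L (link) lines; other line types are ignored with a
#' message giving their count. A link naming an undeclared segment is a
#' validation error.
#'
#' @param path Path to a GFA1 file.
#' @return List of class `assembly_graph` with `segments` (data frame
#'   `id`, `length`) and `links` (data frame `from`, `from_orient`, `to`,
#'   `to_orient`).
#' @export
parse_gfa <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  rec_type <- substr(ln, 1, 1)
  other <- !(rec_type %in% c("S", "L", "#"))
  if (any(other)) {
    message("parse_gfa: ignored ", sum(other), " non-S/L line(s)")
  }
  s_fields <- strsplit(ln[rec_type == "S"], "\t")
  segments <- data.frame(
    id = vapply(s_fields, `[`, "", 2),
    length = vapply(s_fields, function(x) {
      seq_field <- if (length(x) >= 3) x[3] else "*"
      if (seq_field != "*") return(nchar(seq_field))
      tag <- grep("^LN:i:", x, value = TRUE)
      if (length(tag)) as.integer(sub("LN:i:", "", tag[1])) else NA_integer_
    }, numeric(1))
  )
  l_fields <- strsplit(ln[rec_type == "L"], "\t")
  if (length(l_fields)) {
    short <- vapply(l_fields, length, 0L) < 5L
    orient_bad <- vapply(l_fields, function(x) {
      length(x) >= 5 && !(x[3] %in% c("+", "-") && x[5] %in% c("+", "-"))
    }, logical(1))
    if (any(short) || any(orient_bad)) {
      stop("malformed L line(s) (missing field or bad orientation) at: ",
           paste(which(rec_type == "L")[short | orient_bad], collapse = ", "))
    }
  }
  links <- data.frame(
    from = vapply(l_fields, `[`, "", 2),
    from_orient = vapply(l_fields, `[`, "", 3),
    to = vapply(l_fields, `[`, "", 4),
    to_orient = vapply(l_fields, `[`, "", 5)
  )
  assembly_graph(segments, links)
}

#' Construct an assembly graph
#'
#' @param segments Data frame with `id` (and optionally `length`).
#' @param links Data frame with `from`, `from_orient`, `to`, `to_orient`.
#' @export
assembly_graph <- function(segments, links) {
  if (!nrow(links)) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character())
  }
  unknown <- setdiff(c(links$from, links$to), segments$id)
  if (length(unknown)) {
    stop("link references undeclared segment(s): ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(links) &&
      !all(c(links$from_orient, links$to_orient) %in% c("+", "-"))) {
    stop("link orientations must be '+' or '-'")
  }
  structure(list(segments = segments, links = links),
            class = "assembly_graph")
}

# Directed edges over oriented nodes "seg+"/"seg-"; each GFA link implies
# its reverse-complement edge.
oriented_edges <- function(graph) {
  l <- graph$links
  if (!nrow(l)) return(data.frame(from = character(), to = character()))
  flip <- function(o) ifelse(o == "+", "-", "+")
  fwd <- data.frame(from = paste0(l$from, l$from_orient),
                    to = paste0(l$to, l$to_orient))
  rev <- data.frame(from = paste0(l$to, flip(l$to_orient)),
                    to = paste0(l$from, flip(l$from_orient)))
  unique(rbind(fwd, rev))
}

#' Detect simple bubbles in an assembly graph
#'
#' A simple bubble is a source node with exactly two outgoing branches that
#' reconverge on the same sink through vertex-disjoint paths whose interior
#' nodes carry no other links (in-degree and out-degree exactly 1). Detection
#' runs on the oriented-node expansion of the graph; the returned set
#' contains the underlying segment ids of sources, sinks and interiors.
#'
#' @param graph An [assembly_graph()].
#' @return Character vector of segment ids participating in any simple
#'   bubble (empty on branch-free graphs).
#' @export
detect_bubbles <- function(graph) {
  ed <- oriented_edges(graph)
  if (!nrow(ed)) return(character(0))
  nodes <- unique(c(ed$from, ed$to))
  outn <- split(ed$to, factor(ed$from, levels = nodes))
  indeg <- table(factor(ed$to, levels = nodes))
  outdeg <- table(factor(ed$from, levels = nodes))
  seg_of <- function(v) substr(v, 1, nchar(v) - 1)

  walk <- function(start, source) {
    # follow unary nodes; return list(interior, sink) or NULL on failure
    interior <- character(0)
    cur <- start
    for (step in seq_len(length(nodes) + 1)) {
      if (cur == source) return(NULL)
      if (indeg[[cur]] == 1 && outdeg[[cur]] == 1) {
        interior <- c(interior, cur)
        cur <- outn[[cur]][1]
      } else {
        return(list(interior = interior, sink = cur))
      }
    }
    NULL
  }

  hits <- character(0)
  for (s in nodes) {
    children <- outn[[s]]
    if (length(children) != 2) next
    if (children[1] == children[2]) next
    b1 <- walk(children[1], s)
    b2 <- walk(children[2], s)
    if (is.null(b1) || is.null(b2)) next
    t <- b1$sink
    if (!identical(t, b2$sink) || t == s) next
    if (indeg[[t]] != 2) next
    ints <- c(b1$interior, b2$interior)
    if (anyDuplicated(ints) || t %in% ints || s %in% ints) next
    hits <- c(hits, seg_of(c(s, t, ints)))
  }
  sort(unique(hits))
}

#' Read assembler-exported repeat flags
#'
#' @param path TSV with columns `contig_id` and `is_repeat` (boolean).
#' @return Character vector of contig ids flagged as repeats.
#' @export
repeat_flags <- function(path) {
  tb <- read.delim(path, header = TRUE, colClasses = "character")
  stopifnot(all(c("contig_id", "is_repeat") %in% names(tb)))
  if (!nrow(tb)) return(character(0))
  tb$contig_id[parse_bool(tb$is_repeat)]
}
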