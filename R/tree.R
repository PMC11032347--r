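#' Minimum spanning tree over the pocket distance matrix
#'
#' Kruskal's algorithm on the complete graph of pockets with Euclidean
#' descriptor distances as edge weights.  The resulting "pocketome" tree
#' spans all pockets with N-1 edges of minimal total distance; each edge
#' also carries its PSI value.  Weight ties are broken by lexicographic
#' (i, j) pocket-ID order so the tree is deterministic.
#'
#' @param dist A `distance_matrix` from [pairwise_distances()].
#' @return List of class `pocketome_tree` with `nodes` (pocket IDs),
#'   `edges` (data frame `from`, `to`, `distance`, `psi`),
#'   `total_weight`, `sigma` and an (initially empty) `annotations`
#'   data frame.
#' @export
minimum_spanning_tree <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  n <- length(dist$pocket_ids)
  if (n < 2L) stop("need at least 2 pockets")
  if (!all(is.finite(dist$d))) stop("non-finite distances")
  ids <- dist$pocket_ids
  ij <- which(upper.tri(dist$d), arr.ind = TRUE)
  w <- dist$d[ij]
  ord <- order(w, ids[ij[, 1L]], ids[ij[, 2L]], method = "radix")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  sel <- integer(0)
  for (e in ord) {
    a <- find(ij[e, 1L]); b <- find(ij[e, 2L])
    if (a != b) {
      parent[a] <- b
      sel <- c(sel, e)
      if (length(sel) == n - 1L) break
    }
  }
  edges <- data.frame(from = ids[ij[sel, 1L]], to = ids[ij[sel, 2L]],
                      distance = w[sel],
                      psi = psi(w[sel], dist$sigma),
                      stringsAsFactors = FALSE)
  out <- list(nodes = ids, edges = edges,
              total_weight = sum(edges$distance),
              sigma = dist$sigma,
              annotations = data.frame(pocket_id = ids,
                                       stringsAsFactors = FALSE))
  class(out) <- "pocketome_tree"
  out
}

#' @export
print.pocketome_tree <- function(x, ...) {
  cat(sprintf("pocketome_tree: %d pockets, %d edges, total distance %.4f\n",
              length(x$nodes), nrow(x$edges), x$total_weight))
  extra <- setdiff(names(x$annotations), "pocket_id")
  if (length(extra))
    cat("  annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Attach pocket annotations to a tree
#'
#' Annotations (pocket class/subset, volume, exposure, Pfam, CATH, ...)
#' are joined by pocket ID and stored as node attributes for export and
#' colouring.
#'
#' @param tree A `pocketome_tree`.
#' @param annotations Data frame with a `pocket_id` column plus arbitrary
#'   annotation columns.
#' @param allow_missing If `TRUE`, nodes absent from the table get `NA`
#'   annotations; otherwise missing nodes are an error.
#' @return The annotated tree.
#' @export
annotate_tree <- function(tree, annotations, allow_missing = FALSE) {
  stopifnot(inherits(tree, "pocketome_tree"), is.data.frame(annotations))
  if (!"pocket_id" %in% names(annotations))
    stop("'annotations' needs a pocket_id column")
  if (anyDuplicated(annotations$pocket_id))
    stop("duplicate pocket IDs in annotation table")
  hit <- match(tree$nodes, annotations$pocket_id)
  if (any(is.na(hit)) && !allow_missing)
    stop("missing annotation for: ",
         paste(head(tree$nodes[is.na(hit)], 5L), collapse = ", "))
  ann <- annotations[hit, , drop = FALSE]
  ann$pocket_id <- tree$nodes
  rownames(ann) <- NULL
  tree$annotations <- ann
  tree
}

.tree_igraph <- function(tree) {
  g <- igraph::graph_from_data_frame(tree$edges, directed = FALSE,
                                     vertices = tree$annotations)
  g
}

#' Export a pocketome tree
#'
#' `"graphml"` writes all node annotations and edge weights as GraphML
#' attributes (via igraph).  `"html"` writes a single self-contained page
#' (inline data and script, no external resources) with a force-directed
#' layout and a colour-by-annotation selector.
#'
#' @param tree An annotated `pocketome_tree`.
#' @param path Output file path.
#' @param format `"graphml"` or `"html"`.
#' @return Invisibly, `path`.
#' @export
export_tree <- function(tree, path, format = c("graphml", "html")) {
  stopifnot(inherits(tree, "pocketome_tree"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- .tree_igraph(tree)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeLines(.tree_html(tree), path)
  }
  invisible(path)
}

#' Read a pocketome tree back from GraphML
#'
#' @param path GraphML file written by [export_tree()].
#' @return A `pocketome_tree` (sigma is recovered from edge attributes
#'   when present, otherwise `NA`).
#' @export
read_tree_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vd <- igraph::as_data_frame(g, what = "vertices")
  nodes <- vd$name
  ann <- vd
  names(ann)[names(ann) == "name"] <- "pocket_id"
  edges <- data.frame(from = ed$from, to = ed$to,
                      distance = ed$distance,
                      psi = if ("psi" %in% names(ed)) ed$psi else NA_real_,
                      stringsAsFactors = FALSE)
  sigma <- NA_real_
  if (all(c("distance", "psi") %in% names(ed)) && nrow(ed)) {
    ok <- ed$psi > 0 & ed$psi < 1 & ed$distance > 0
    if (any(ok))
      sigma <- sqrt(ed$distance[ok][1L]^2 / (-2 * log(ed$psi[ok][1L])))
  }
  out <- list(nodes = nodes, edges = edges,
              total_weight = sum(edges$distance),
              sigma = sigma, annotations = ann)
  class(out) <- "pocketome_tree"
  out
}

#' Label homogeneity of tree branches
#'
#' Fraction of tree edges whose two endpoints carry the same value of an
#' annotation field; edges with a missing label on either end are
#' excluded.  A pocketome whose branches group pockets of one subset or
#' family scores near 1.
#'
#' @param tree An annotated `pocketome_tree`.
#' @param label_field Name of the annotation column.
#' @return Proportion in `[0, 1]`.
#' @export
branch_homogeneity <- function(tree, label_field) {
  stopifnot(inherits(tree, "pocketome_tree"))
  if (!label_field %in% names(tree$annotations))
    stop("annotation field not found: ", label_field)
  lab <- setNames(tree$annotations[[label_field]], tree$annotations$pocket_id)
  la <- lab[tree$edges$from]
  lb <- lab[tree$edges$to]
  ok <- !is.na(la) & !is.na(lb)
  if (!any(ok)) stop("no edge has labels on both endpoints")
  mean(la[ok] == lb[ok])
}

# self-contained interactive HTML export: inline JSON + minimal SVG
# force layout, no external resources.
.tree_html <- function(tree) {
  ann <- tree$annotations
  payload <- jsonlite::toJSON(list(
    nodes = ann,
    edges = tree$edges
  ), dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA)
  fields <- setdiff(names(ann), "pocket_id")
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>pocketome tree</title>",
    "<style>body{font-family:sans-serif;margin:0}#bar{padding:6px;background:#eee}",
    "svg{display:block}circle{stroke:#333;stroke-width:.5}line{stroke:#999}",
    "text.lbl{font-size:9px;fill:#555}</style></head><body>",
    "<div id=\"bar\">colour by: <select id=\"field\"></select></div>",
    "<svg id=\"view\" width=\"900\" height=\"700\"></svg>",
    paste0("<script>var data=", payload, ";"),
    paste0("var fields=", jsonlite::toJSON(fields), ";"),
    "var sel=document.getElementById('field');",
    "fields.forEach(function(f){var o=document.createElement('option');o.value=f;o.textContent=f;sel.appendChild(o);});",
    "var W=900,H=700,N=data.nodes.length;",
    "var idx={};data.nodes.forEach(function(d,i){idx[d.pocket_id]=i;});",
    "var px=[],py=[],vx=[],vy=[];",
    "for(var i=0;i<N;i++){var a=2*Math.PI*i/N;px.push(W/2+200*Math.cos(a));py.push(H/2+200*Math.sin(a));vx.push(0);vy.push(0);}",
    "var E=data.edges.map(function(e){return [idx[e.from],idx[e.to]];});",
    "for(var it=0;it<300;it++){",
    " for(var i=0;i<N;i++){for(var j=i+1;j<N;j++){var dx=px[i]-px[j],dy=py[i]-py[j];var d2=dx*dx+dy*dy+1;var f=1200/d2;vx[i]+=f*dx;vy[i]+=f*dy;vx[j]-=f*dx;vy[j]-=f*dy;}}",
    " E.forEach(function(e){var dx=px[e[0]]-px[e[1]],dy=py[e[0]]-py[e[1]];var d=Math.sqrt(dx*dx+dy*dy)+1e-6;var f=0.02*(d-40)/d;vx[e[0]]-=f*dx;vy[e[0]]-=f*dy;vx[e[1]]+=f*dx;vy[e[1]]+=f*dy;});",
    " for(var i=0;i<N;i++){px[i]=Math.min(W-10,Math.max(10,px[i]+vx[i]*0.05));py[i]=Math.min(H-10,Math.max(10,py[i]+vy[i]*0.05));vx[i]*=0.6;vy[i]*=0.6;}",
    "}",
    "var svg=document.getElementById('view');var SVGNS='http://www.w3.org/2000/svg';",
    "function colour(f){var vals=data.nodes.map(function(d){return d[f];});",
    " var uniq=vals.filter(function(v,i){return vals.indexOf(v)===i;});",
    " var numeric=vals.every(function(v){return v===null||typeof v==='number';});",
    " return vals.map(function(v){if(v===null)return '#bbb';",
    "  if(numeric){var mn=Math.min.apply(null,vals.filter(function(x){return x!==null;}));var mx=Math.max.apply(null,vals.filter(function(x){return x!==null;}));var t=mx>mn?(v-mn)/(mx-mn):0.5;var h=240-240*t;return 'hsl('+h+',70%,50%)';}",
    "  var k=uniq.indexOf(v);return 'hsl('+(k*137.5%360)+',65%,50%)';});}",
    "function draw(){svg.textContent='';",
    " E.forEach(function(e){var l=document.createElementNS(SVGNS,'line');l.setAttribute('x1',px[e[0]]);l.setAttribute('y1',py[e[0]]);l.setAttribute('x2',px[e[1]]);l.setAttribute('y2',py[e[1]]);svg.appendChild(l);});",
    " var cols=colour(sel.value||fields[0]);",
    " data.nodes.forEach(function(d,i){var c=document.createElementNS(SVGNS,'circle');c.setAttribute('cx',px[i]);c.setAttribute('cy',py[i]);c.setAttribute('r',6);c.setAttribute('fill',cols[i]);var t=document.createElementNS(SVGNS,'title');t.textContent=d.pocket_id;c.appendChild(t);svg.appendChild(c);});",
    "}",
    "sel.addEventListener('change',draw);draw();",
    "</script></body></html>")
}
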