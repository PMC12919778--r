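#' @include scores.R
NULL

#' Assemble a report bundle
#'
#' Collects projections, their structure scores, probe results and the
#' per-item labels needed for colouring and class filtering into one
#' validated object. A colour palette over the classes of \code{variable}
#' is generated deterministically unless supplied.
#'
#' @param set The \linkS4class{EmbeddingSet} the projections came from
#'   (supplies metadata labels for every projected item).
#' @param projections List of \linkS4class{ProjectionResult}.
#' @param scores List of \linkS4class{StructureScores}, aligned with
#'   \code{projections}.
#' @param variable A \linkS4class{VariableSpec} or variable name: the
#'   default colouring variable.
#' @param probeResults Optional list of \linkS4class{ProbeResult}.
#' @param rawProjections Optional list of raw-pixel companion
#'   \linkS4class{ProjectionResult}s shown side by side.
#' @param palette Optional named colour vector covering the classes of
#'   \code{variable}.
#' @return A \linkS4class{ReportBundle}.
#' @export
reportBundle <- function(set, projections, scores, variable,
                         probeResults = list(), rawProjections = list(),
                         palette = NULL) {
  if (is.character(variable)) variable <- variableSpec(variable)
  allIds <- unique(unlist(lapply(c(projections, rawProjections),
                                 function(p) p@ids)))
  md <- itemMeta(set)
  labels <- lapply(stats::setNames(nm = colnames(md)), function(v)
    itemMeta(set, v)[allIds])
  if (!length(labels))
    flensError("the set has no metadata variables to label by")
  classes <- sort(unique(labels[[variable@name]]))
  if (is.null(palette)) {
    palette <- stats::setNames(
      grDevices::hcl.colors(max(3L, length(classes)), "Dark 3")[seq_along(classes)],
      classes)
  }
  new("ReportBundle", projections = projections, scores = scores,
      probeResults = probeResults, variable = variable, labels = labels,
      palette = palette, rawProjections = rawProjections)
}

bundlePayload <- function(bundle) {
  projPayload <- function(p, kind) list(
    kind = kind, method = p@params@method,
    nNeighbors = p@params@nNeighbors, minDist = p@params@minDist,
    seed = p@params@seed, ids = p@ids,
    x = unname(p@coords[, 1]), y = unname(p@coords[, 2]))
  scorePayload <- function(s) list(
    silhouette = s@silhouette, ari = s@ari,
    knnPreservation = s@knnPreservation, cpd = s@cpd,
    kUsed = s@kUsed, nScored = s@nScored)
  probePayload <- function(r) list(
    variable = r@provenance$variable, accuracy = r@accuracy,
    ciLow = r@ciLow, ciHigh = r@ciHigh, kappaMean = r@kappaMean,
    nTest = r@nTest, nClasses = r@nClasses)
  list(
    variable = bundle@variable@name,
    variables = names(bundle@labels),
    labels = lapply(bundle@labels, function(v) as.list(v)),
    palette = as.list(bundle@palette),
    projections = lapply(bundle@projections, projPayload, kind = "embedding"),
    rawProjections = lapply(bundle@rawProjections, projPayload, kind = "raw"),
    scores = lapply(bundle@scores, scorePayload),
    probes = lapply(bundle@probeResults, probePayload))
}

#' Write a self-contained interactive HTML report
#'
#' One HTML file, no network dependencies: every projection is a zoomable,
#' pannable scatter panel laid out on the (nNeighbors x minDist) grid,
#' with a colouring-variable selector, per-class show/hide toggles, raw-
#' pixel companion panels side by side when present, and a score table.
#' All data are embedded as JSON inside the document, so the file can be
#' shared as-is.
#'
#' @param bundle A \linkS4class{ReportBundle}.
#' @param outPath Destination \code{.html} path.
#' @return \code{outPath}, invisibly.
#' @seealso [exportScoresTable()]
#' @export
buildReport <- function(bundle, outPath) {
  stopifnot(is(bundle, "ReportBundle"))
  validObject(bundle)
  payload <- jsonlite::toJSON(bundlePayload(bundle), auto_unbox = TRUE,
                              digits = 10, null = "null", na = "null")
  html <- sub("__FLENS_DATA__", payload, reportTemplate(), fixed = TRUE)
  ok <- tryCatch({ writeLines(html, outPath); TRUE },
                 error = function(e) flensError(
                   sprintf("cannot write %s: %s", outPath, conditionMessage(e))))
  invisible(outPath)
}

#' Export the score table as delimited text
#'
#' One row per projection (parameters plus the four structure scores),
#' probe rows appended (accuracy, CI bounds, kappa). Undefined kappa is
#' rendered as \code{NA}.
#'
#' @param bundle A \linkS4class{ReportBundle}.
#' @param outPath Destination \code{.tsv} path.
#' @return \code{outPath}, invisibly.
#' @export
exportScoresTable <- function(bundle, outPath) {
  stopifnot(is(bundle, "ReportBundle"))
  if (!length(bundle@scores)) flensError("bundle has no scores")
  num <- function(x) sprintf("%.9g", x)
  rows <- lapply(seq_along(bundle@projections), function(i) {
    p <- bundle@projections[[i]]; s <- bundle@scores[[i]]
    data.frame(row_type = "projection", method = p@params@method,
               n_neighbors = p@params@nNeighbors,
               min_dist = p@params@minDist,
               silhouette = num(s@silhouette), ari = num(s@ari),
               knn_preservation = num(s@knnPreservation), cpd = num(s@cpd),
               accuracy = NA, ci_low = NA, ci_high = NA, kappa_mean = NA,
               n = s@nScored, stringsAsFactors = FALSE)
  })
  probeRows <- lapply(bundle@probeResults, function(r) {
    data.frame(row_type = "probe",
               method = r@provenance$variable %||% "probe",
               n_neighbors = NA, min_dist = NA, silhouette = NA, ari = NA,
               knn_preservation = NA, cpd = NA,
               accuracy = num(r@accuracy), ci_low = num(r@ciLow),
               ci_high = num(r@ciHigh),
               kappa_mean = if (is.na(r@kappaMean)) NA else num(r@kappaMean),
               n = r@nTest, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, probeRows))
  utils::write.table(tab, outPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(outPath)
}

reportTemplate <- function() {
  paste0('<!DOCTYPE html>
<html lang="en">
<head>
<meta charset="utf-8">
<title>featurelens report</title>
<style>
 body { font-family: system-ui, sans-serif; margin: 1rem; background: #fafafa; }
 h1 { font-size: 1.3rem; }
 .controls { margin-bottom: 1rem; display: flex; gap: 1.5rem; flex-wrap: wrap; }
 .panelgrid { display: flex; flex-wrap: wrap; gap: 1rem; }
 .panel { background: #fff; border: 1px solid #ccc; border-radius: 6px; padding: 6px; }
 .panel h3 { margin: 0 0 4px 0; font-size: 0.85rem; font-weight: 600; }
 .panel svg { cursor: grab; }
 table { border-collapse: collapse; margin-top: 1rem; font-size: 0.85rem; }
 td, th { border: 1px solid #bbb; padding: 3px 8px; }
 .legend label { margin-right: 0.8rem; font-size: 0.85rem; }
 .swatch { display: inline-block; width: 10px; height: 10px; border-radius: 5px; margin-right: 3px; }
</style>
</head>
<body>
<h1>featurelens embedding inspection report</h1>
<div class="controls">
 <div><label>Colour by:
   <select id="varsel"></select></label></div>
 <div class="legend" id="legend"></div>
</div>
<div class="panelgrid" id="panels"></div>
<div id="scoretable"></div>
<script type="application/json" id="flens-data">__FLENS_DATA__</script>
<script>
(function () {
 "use strict";
 var data = JSON.parse(document.getElementById("flens-data").textContent);
 var curVar = data.variable;
 var hidden = {};
 var W = 320, H = 320, PAD = 10;

 function palFor(variable) {
   if (variable === data.variable) return data.palette;
   var classes = classesFor(variable), pal = {},
       hues = [210, 30, 120, 280, 60, 330, 170, 240, 0, 90];
   classes.forEach(function (c, i) {
     pal[c] = "hsl(" + hues[i % hues.length] + ",65%," + (35 + 12 * Math.floor(i / hues.length)) + "%)";
   });
   return pal;
 }
 function classesFor(variable) {
   var lab = data.labels[variable], seen = {};
   Object.keys(lab).forEach(function (id) { seen[lab[id]] = true; });
   return Object.keys(seen).sort();
 }

 function makePanel(proj, idx) {
   var div = document.createElement("div");
   div.className = "panel";
   div.dataset.kind = proj.kind;
   var title = proj.kind + " | " + proj.method +
     " | n_neighbors=" + proj.nNeighbors + " min_dist=" + proj.minDist;
   var h = document.createElement("h3");
   h.textContent = title;
   div.appendChild(h);
   var svg = document.createElementNS("http://www.w3.org/2000/svg", "svg");
   svg.setAttribute("width", W); svg.setAttribute("height", H);
   var xs = proj.x, ys = proj.y;
   var xmin = Math.min.apply(null, xs), xmax = Math.max.apply(null, xs);
   var ymin = Math.min.apply(null, ys), ymax = Math.max.apply(null, ys);
   var sx = (W - 2 * PAD) / ((xmax - xmin) || 1);
   var sy = (H - 2 * PAD) / ((ymax - ymin) || 1);
   var g = document.createElementNS("http://www.w3.org/2000/svg", "g");
   svg.appendChild(g);
   proj.ids.forEach(function (id, i) {
     var c = document.createElementNS("http://www.w3.org/2000/svg", "circle");
     c.setAttribute("cx", PAD + (xs[i] - xmin) * sx);
     c.setAttribute("cy", H - PAD - (ys[i] - ymin) * sy);
     c.setAttribute("r", 2.2);
     c.dataset.id = id;
     g.appendChild(c);
   });
   var view = { tx: 0, ty: 0, k: 1 };
   function apply() {
     g.setAttribute("transform",
       "translate(" + view.tx + "," + view.ty + ") scale(" + view.k + ")");
   }
   svg.addEventListener("wheel", function (ev) {
     ev.preventDefault();
     var f = ev.deltaY < 0 ? 1.15 : 1 / 1.15;
     var r = svg.getBoundingClientRect();
     var mx = ev.clientX - r.left, my = ev.clientY - r.top;
     view.tx = mx - f * (mx - view.tx);
     view.ty = my - f * (my - view.ty);
     view.k *= f;
     apply();
   });
   var drag = null;
   svg.addEventListener("mousedown", function (ev) {
     drag = { x: ev.clientX, y: ev.clientY, tx: view.tx, ty: view.ty };
   });
   window.addEventListener("mousemove", function (ev) {
     if (!drag) return;
     view.tx = drag.tx + (ev.clientX - drag.x);
     view.ty = drag.ty + (ev.clientY - drag.y);
     apply();
   });
   window.addEventListener("mouseup", function () { drag = null; });
   div.appendChild(svg);
   return div;
 }

 function recolor() {
   var lab = data.labels[curVar], pal = palFor(curVar);
   document.querySelectorAll("#panels circle").forEach(function (c) {
     var cls = lab[c.dataset.id];
     c.setAttribute("fill", pal[cls] || "#888");
     c.setAttribute("visibility", hidden[cls] ? "hidden" : "visible");
   });
   var leg = document.getElementById("legend");
   leg.innerHTML = "";
   classesFor(curVar).forEach(function (cls) {
     var lbl = document.createElement("label");
     var cb = document.createElement("input");
     cb.type = "checkbox"; cb.checked = !hidden[cls];
     cb.addEventListener("change", function () {
       hidden[cls] = !cb.checked; recolor();
     });
     var sw = document.createElement("span");
     sw.className = "swatch"; sw.style.background = pal[cls];
     lbl.appendChild(cb); lbl.appendChild(sw);
     lbl.appendChild(document.createTextNode(cls));
     leg.appendChild(lbl);
   });
 }

 var panels = document.getElementById("panels");
 data.projections.forEach(function (p, i) {
   panels.appendChild(makePanel(p, i));
   if (data.rawProjections[i])
     panels.appendChild(makePanel(data.rawProjections[i], i));
 });

 var sel = document.getElementById("varsel");
 data.variables.forEach(function (v) {
   var o = document.createElement("option");
   o.value = v; o.textContent = v;
   if (v === curVar) o.selected = true;
   sel.appendChild(o);
 });
 sel.addEventListener("change", function () {
   curVar = sel.value; hidden = {}; recolor();
 });

 var st = document.getElementById("scoretable");
 var rows = data.scores.map(function (s, i) {
   var p = data.projections[i];
   return "<tr><td>nn=" + p.nNeighbors + " md=" + p.minDist + "</td><td>" +
     s.silhouette.toFixed(4) + "</td><td>" + s.ari.toFixed(4) + "</td><td>" +
     s.knnPreservation.toFixed(4) + "</td><td>" + s.cpd.toFixed(4) + "</td></tr>";
 }).join("");
 var probeRows = data.probes.map(function (r) {
   var kap = (r.kappaMean === null || r.kappaMean === undefined) ? "NA"
     : r.kappaMean.toFixed(4);
   return "<tr><td>probe: " + r.variable + "</td><td colspan=2>acc " +
     r.accuracy.toFixed(4) + " [" + r.ciLow.toFixed(4) + ", " +
     r.ciHigh.toFixed(4) + "]</td><td colspan=2>kappa " + kap + "</td></tr>";
 }).join("");
 st.innerHTML = "<table><tr><th>projection</th><th>silhouette</th>" +
   "<th>ARI</th><th>KNN</th><th>CPD</th></tr>" + rows + probeRows + "</table>";
 recolor();
})();
</script>
</body>
</html>')
}
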