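## Offline workflow runner: the programmatic surface behind the
## command-line wrapper (inst/scripts/netcompare.R). Each invocation maps
## one subcommand onto the package functions, writes machine-readable
## outputs into an output directory and records a JSON run manifest
## (inputs with checksums, parameters, package version, per-stage timings).

.logMsg <- function(level, threshold, ...) {
    levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
    if (levels[[level]] >= levels[[threshold]])
        message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run one comparison workflow end to end
#'
#' Loads the input edge lists, executes one named workflow and writes its
#' result files plus a \code{manifest.json} into \code{outDir}. Available
#' workflows: \code{preview} (global property table), \code{sets}
#' (intersection regions + UpSet rows), \code{properties} (all centralities
#' per network), \code{delta} (one measure across networks), \code{paths}
#' (shortest-path matrix), \code{communities} (partitions + merged table),
#' \code{transitions} (pairwise transition reports), \code{cliques} (clique
#' table + tracking), \code{similarity} (Jaccard matrix, newick dendrogram,
#' radar distances), \code{union-viz} (annotated union graph JSON) and
#' \code{synth} (random network generation; needs no inputs).
#'
#' Outputs for a fixed configuration and seed are deterministic; partial
#' outputs are removed if the run fails.
#'
#' @param workflow workflow name (see above).
#' @param inputs character vector of edge-list file paths (2--8; ignored by
#'   \code{synth}).
#' @param outDir output directory (created if needed).
#' @param labels optional network labels (default: file names).
#' @param delimiter,sourceCol,targetCol,weightCol,hasHeader parsing options,
#'   applied to every input (see \code{\link{parseEdgeList}}).
#' @param selected labels to analyse (default: all).
#' @param elementKind \code{"node"} or \code{"edge"} for set workflows.
#' @param sortBy UpSet row order (see \code{\link{upsetRows}}).
#' @param source,target node pair for \code{paths}.
#' @param weighted weighted shortest-path mode.
#' @param measure centrality measure for \code{delta}.
#' @param k minimum clique size for \code{cliques}.
#' @param n,m,replicates,overlap,structure generation parameters for
#'   \code{synth} (structure \code{"random"} or \code{"overlapping_family"}).
#' @param seed integer seed for any randomised step.
#' @param logLevel \code{"debug"}, \code{"info"}, \code{"warn"} or
#'   \code{"quiet"}.
#' @return invisibly, a character vector of the files written.
#' @export
runWorkflow <- function(workflow, inputs = character(0), outDir,
                        labels = NULL, delimiter = "\t", sourceCol = 1L,
                        targetCol = 2L, weightCol = NULL, hasHeader = FALSE,
                        selected = NULL, elementKind = "edge",
                        sortBy = "set_cardinality",
                        source = NULL, target = NULL, weighted = FALSE,
                        measure = "degree", k = 3L,
                        n = 500L, m = 1000L, replicates = 3L, overlap = 0.8,
                        structure = "random", seed = 1L,
                        logLevel = "info") {
    workflow <- match.arg(workflow,
        c("preview", "sets", "properties", "delta", "paths", "communities",
          "transitions", "cliques", "similarity", "union-viz", "synth"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    timings <- list()
    out <- function(name) {
        p <- file.path(outDir, name)
        written <<- c(written, p)
        p
    }
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- force(expr)
        timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        .logMsg("info", logLevel,
                sprintf("stage '%s' done in %.3fs", name, timings[[name]]))
        res
    }
    runBody <- function() {
        collection <- NULL
        if (workflow != "synth") {
            if (length(inputs) < 2L)
                stop("at least 2 input networks are required")
            if (is.null(labels))
                labels <- sub("\\.[^.]*$", "", basename(inputs))
            collection <- stage("load", {
                nets <- mapply(function(p, lab)
                    readEdgeList(p, label = lab, delimiter = delimiter,
                                 sourceCol = sourceCol, targetCol = targetCol,
                                 weightCol = weightCol, hasHeader = hasHeader),
                    inputs, labels, SIMPLIFY = FALSE)
                loadCollection(nets)
            })
        }
        switch(workflow,
        preview = stage("preview", {
            utils::write.table(collectionProperties(collection),
                               out("global_properties.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }),
        sets = stage("sets", {
            rm <- computeRegions(collection, selected, elementKind)
            regionsToJSON(rm, out("regions.json"))
            writeRegionTable(rm, out("regions.tsv"))
            rows <- upsetRows(rm, sortBy)
            rows$members <- vapply(rows$members, paste, character(1),
                                   collapse = ",")
            utils::write.table(rows, out("upset_rows.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }),
        properties = stage("properties", {
            for (lab in .resolveSelection(collection, selected))
                writeCentralityTable(
                    nodeCentralities(getNetwork(collection, lab)),
                    out(paste0("centralities_", lab, ".tsv")))
        }),
        delta = stage("delta", {
            writeCentralityTable(
                deltaCentrality(collection, measure, selected = selected),
                out(paste0("delta_", measure, ".tsv")))
        }),
        paths = stage("paths", {
            if (is.null(source) || is.null(target))
                stop("workflow 'paths' requires --source and --target")
            pm <- pathMatrix(collection, source, target, selected, weighted)
            pathMatrixToJSON(pm, out("path_matrix.json"))
            writePathTable(pm, out("paths.tsv"))
        }),
        communities = stage("communities", {
            sel <- .resolveSelection(collection, selected)
            parts <- lapply(sel, function(lab)
                detectCommunities(getNetwork(collection, lab)))
            names(parts) <- sel
            for (lab in sel)
                partitionToJSON(parts[[lab]],
                                out(paste0("partition_", lab, ".json")))
            writeCommunityTable(communityTable(collection, sel, parts),
                                out("community_table.tsv"))
        }),
        transitions = stage("transitions", {
            sel <- .resolveSelection(collection, selected)
            parts <- lapply(sel, function(lab)
                detectCommunities(getNetwork(collection, lab)))
            names(parts) <- sel
            for (i in seq_len(length(sel) - 1L))
                for (j in (i + 1L):length(sel)) {
                    rep <- communityTransitions(parts[[i]], parts[[j]])
                    transitionToJSON(rep, out(sprintf("transitions_%s_%s.json",
                                                      sel[i], sel[j])))
                }
        }),
        cliques = stage("cliques", {
            tab <- cliqueTable(collection, selected, k = k)
            writeCliqueTable(tab, out("cliques.tsv"))
            if (nrow(tab))
                trackingToJSON(trackClique(tab$members[[1L]], collection,
                                           selected),
                               out("top_clique_tracking.json"))
        }),
        similarity = stage("similarity", {
            sm <- edgeJaccardMatrix(collection, selected)
            writeSimilarityMatrix(sm, out("edge_jaccard.tsv"))
            dendrogramNewick(clusterNetworks(sm), out("dendrogram.nwk"))
            radarDistancesToJSON(unionDistances(collection, selected),
                                 out("union_distances.json"))
        }),
        `union-viz` = stage("union", {
            unionGraphToJSON(unionGraph(collection, selected),
                             out("union_graph.json"))
        }),
        synth = stage("synth", {
            nets <- if (structure == "overlapping_family")
                generateFamily(n, m, networks = replicates, overlap = overlap,
                               seed = seed)@networks
            else
                generateRandom(n, m, replicates = replicates, seed = seed)
            for (nw in nets)
                writeEdgeList(nw, out(paste0(networkLabel(nw), ".tsv")))
        }))
        manifest <- list(
            workflow = workflow,
            inputs = if (length(inputs))
                lapply(inputs, function(p)
                    list(path = p, md5 = unname(tools::md5sum(p))))
            else list(),
            parameters = list(delimiter = delimiter, sourceCol = sourceCol,
                              targetCol = targetCol, weightCol = weightCol,
                              hasHeader = hasHeader, selected = selected,
                              elementKind = elementKind, sortBy = sortBy,
                              source = source, target = target,
                              weighted = weighted, measure = measure, k = k,
                              n = n, m = m, replicates = replicates,
                              overlap = overlap, structure = structure,
                              seed = seed),
            package_version = as.character(utils::packageVersion("NetCompare")),
            timings_seconds = timings,
            outputs = basename(written))
        writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    pretty = TRUE, null = "null"),
                   out("manifest.json"))
    }
    tryCatch(runBody(), error = function(e) {
        unlink(written)
        stop("workflow '", workflow, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
    .logMsg("info", logLevel, sprintf("workflow '%s' wrote %d file(s) to %s",
                                      workflow, length(written), outDir))
    invisible(written)
}
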