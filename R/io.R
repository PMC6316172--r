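# Readers/writers for the package's plain-text formats: network definition
# files, experiment (constraint) files, expression CSV panels and outcome
# tables. Machine outputs are JSON via jsonlite; the line-oriented inputs
# are designed to be hand-editable.

fmt_ranges <- function(ints) {
  ints <- sort(unique(as.integer(ints)))
  runs <- split(ints, cumsum(c(1L, diff(ints) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else paste0(r[1L], "-", r[length(r)])
  }, ""), collapse = ",")
}

parse_ranges <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      ab[1L]:ab[2L]
    } else {
      as.integer(p)
    }
  }))
}

#' Read and write network definition files
#'
#' Line-oriented format: \code{component NAME gene|signal [conditions=SPEC]}
#' declares a component (\code{SPEC} like \code{0-8} or \code{0,2,4-6});
#' \code{SOURCE -> TARGET definite|optional} / \code{SOURCE -| TARGET ...}
#' declare positive / negative interactions. \code{#} starts a comment. A
#' JSON mirror of the same schema (extension \code{.json}) is also
#' accepted.
#'
#' @param path file path
#' @return an [abn()]
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    allowed <- lapply(obj$allowed_conditions, as.integer)
    return(abn(obj$components, obj$interactions, allowed))
  }
  lines <- readLines(path)
  comps <- list()
  ia <- list()
  allowed <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "component") {
      if (length(tok) < 3L || !tok[3L] %in% c("gene", "signal")) {
        stop("line ", i, ": malformed component declaration")
      }
      comps[[length(comps) + 1L]] <- data.frame(name = tok[2L],
                                                role = tok[3L])
      if (length(tok) >= 4L) {
        if (!grepl("^conditions=", tok[4L])) {
          stop("line ", i, ": expected conditions=...")
        }
        allowed[[tok[2L]]] <- parse_ranges(sub("^conditions=", "", tok[4L]))
      }
    } else {
      if (length(tok) != 4L || !tok[2L] %in% c("->", "-|") ||
          !tok[4L] %in% c("definite", "optional")) {
        stop("line ", i, ": malformed interaction (expected ",
             "'SOURCE -> TARGET definite|optional')")
      }
      ia[[length(ia) + 1L]] <-
        data.frame(source = tok[1L], target = tok[3L],
                   sign = if (tok[2L] == "->") "positive" else "negative",
                   definite = tok[4L] == "definite")
    }
  }
  if (!length(comps)) stop("no components declared in ", path)
  tryCatch(
    abn(do.call(rbind, comps),
        if (length(ia)) do.call(rbind, ia) else NULL, allowed),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
}

#' @rdname read_network
#' @param network an [abn()]
#' @export
write_network <- function(network, path) {
  lines <- character()
  for (comp in network$components) {
    role <- network$roles[[comp]]
    lines <- c(lines, if (role == "gene") {
      sprintf("component %s gene conditions=%s", comp,
              fmt_ranges(network$allowed_conditions[[comp]]))
    } else {
      sprintf("component %s signal", comp)
    })
  }
  ia <- network$interactions
  for (k in seq_len(nrow(ia))) {
    lines <- c(lines, sprintf("%s %s %s %s", ia$source[k],
                              if (ia$sign[k] == "positive") "->" else "-|",
                              ia$target[k],
                              if (ia$definite[k]) "definite" else "optional"))
  }
  writeLines(lines, path)
  invisible(path)
}

fmt_state <- function(state) {
  paste(sprintf("%s=%s", names(state), ifelse(state, "high", "low")),
        collapse = " ")
}

parse_state <- function(toks) {
  if (!length(toks)) return(stats::setNames(logical(), character()))
  kv <- strsplit(toks, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L |
    !vapply(kv, function(x) x[2L] %in% c("high", "low"), NA)
  if (any(bad)) stop("malformed state token: ", toks[bad][1L])
  stats::setNames(vapply(kv, function(x) x[2L] == "high", NA),
                  vapply(kv, `[`, "", 1L))
}

#' Read and write experiment (constraint) files
#'
#' Each block starts \code{experiment NAME bound=N} and lists
#' \code{input SIG=on|off ...}, \code{force NAME high|low [from=S] [to=S]},
#' \code{initial NAME=high|low ...} and
#' \code{expect step A..B reached|never|held|stable NAME=high|low ...}
#' lines. \code{comparative NAME treated=EXP reference=EXP} blocks with a
#' \code{target NAME=high|low ...} line encode paired-trajectory
#' constraints over two previously declared experiment blocks.
#'
#' @param path file path
#' @return list with \code{experiments} and \code{comparatives}
#' @export
read_experiments <- function(path) {
  lines <- readLines(path)
  experiments <- list()
  comparatives <- list()
  cur <- NULL
  finish <- function(cur) {
    if (is.null(cur)) return()
    if (cur$kind == "experiment") {
      sched <- schedule(cur$inputs, if (length(cur$clamps))
        do.call(rbind, cur$clamps))
      experiments[[length(experiments) + 1L]] <<-
        experiment(cur$name, sched, cur$initial, cur$expects, cur$bound)
    } else {
      tr <- experiments[[which(vapply(experiments, function(e) e$name, "")
                               == cur$treated)[1L]]]
      rf <- experiments[[which(vapply(experiments, function(e) e$name, "")
                               == cur$reference)[1L]]]
      comparatives[[length(comparatives) + 1L]] <<-
        comparative(cur$name, tr, rf, cur$target)
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "experiment") {
      finish(cur)
      bound <- 20L
      if (length(tok) >= 3L && grepl("^bound=", tok[3L])) {
        bound <- as.integer(sub("^bound=", "", tok[3L]))
      }
      cur <- list(kind = "experiment", name = tok[2L], bound = bound,
                  inputs = stats::setNames(logical(), character()),
                  clamps = list(), initial = stats::setNames(logical(),
                                                             character()),
                  expects = list())
    } else if (tok[1L] == "comparative") {
      finish(cur)
      kv <- parse_kv(tok[-(1:2)])
      cur <- list(kind = "comparative", name = tok[2L],
                  treated = kv[["treated"]], reference = kv[["reference"]],
                  target = NULL)
    } else if (is.null(cur)) {
      stop("line ", i, ": directive outside a block")
    } else if (tok[1L] == "input") {
      kv <- strsplit(tok[-1L], "=", fixed = TRUE)
      vals <- vapply(kv, function(x) x[2L] == "on", NA)
      cur$inputs <- c(cur$inputs,
                      stats::setNames(vals, vapply(kv, `[`, "", 1L)))
    } else if (tok[1L] == "force") {
      kv <- parse_kv(tok[-(1:3)])
      from <- if ("from" %in% names(kv)) as.numeric(kv[["from"]]) else 0
      to <- if ("to" %in% names(kv)) {
        if (kv[["to"]] == "inf") Inf else as.numeric(kv[["to"]])
      } else Inf
      cur$clamps[[length(cur$clamps) + 1L]] <-
        clamp(tok[2L], tok[3L] == "high", from, to)
    } else if (tok[1L] == "initial") {
      cur$initial <- c(cur$initial, parse_state(tok[-1L]))
    } else if (tok[1L] == "expect") {
      if (tok[2L] != "step") stop("line ", i, ": expected 'expect step ...'")
      ab <- as.integer(strsplit(tok[3L], "..", fixed = TRUE)[[1L]])
      if (length(ab) == 1L) ab <- c(ab, ab)
      cur$expects[[length(cur$expects) + 1L]] <-
        expectation(tok[4L], parse_state(tok[-(1:4)]), ab[1L], ab[2L])
    } else if (tok[1L] == "target") {
      cur$target <- parse_state(tok[-1L])
    } else {
      stop("line ", i, ": unknown directive '", tok[1L], "'")
    }
  }
  finish(cur)
  list(experiments = experiments, comparatives = comparatives)
}

parse_kv <- function(toks) {
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' @rdname read_experiments
#' @param constraints list with \code{experiments}/\code{comparatives}
#'   (as from [read_experiments()] or [builtin_resetting_constraints()]),
#'   or a flat list of constraints
#' @export
write_experiments <- function(constraints, path) {
  flat <- flatten_constraints(constraints)
  exps <- Filter(function(x) inherits(x, "experiment"), flat)
  cmps <- Filter(function(x) inherits(x, "comparative"), flat)
  # comparatives reference experiment blocks; emit any missing ones
  have <- vapply(exps, function(e) e$name, "")
  for (cm in cmps) {
    for (e in list(cm$treated, cm$reference)) {
      if (!e$name %in% have) {
        exps <- c(exps, list(e))
        have <- c(have, e$name)
      }
    }
  }
  lines <- character()
  for (e in exps) {
    lines <- c(lines, sprintf("experiment %s bound=%d", e$name, e$bound))
    if (length(e$sched$inputs)) {
      lines <- c(lines, paste("  input", paste(
        sprintf("%s=%s", names(e$sched$inputs),
                ifelse(e$sched$inputs, "on", "off")), collapse = " ")))
    }
    cl <- e$sched$clamps
    for (k in seq_len(nrow(cl))) {
      lines <- c(lines, sprintf("  force %s %s from=%s to=%s",
                                cl$component[k],
                                if (cl$value[k]) "high" else "low",
                                format(cl$from[k]),
                                if (is.finite(cl$to[k]))
                                  format(cl$to[k]) else "inf"))
    }
    if (length(e$initial)) {
      lines <- c(lines, paste("  initial", fmt_state(e$initial)))
    }
    for (ex in e$expectations) {
      rg <- resolve_range(ex, e$bound)
      lines <- c(lines, sprintf("  expect step %d..%d %s %s",
                                rg["from"], rg["to"], ex$modality,
                                fmt_state(ex$state)))
    }
  }
  for (cm in cmps) {
    lines <- c(lines,
               sprintf("comparative %s treated=%s reference=%s",
                       cm$name, cm$treated$name, cm$reference$name),
               paste("  target", fmt_state(cm$target)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression dataset panels
#'
#' Each dataset is a CSV (genes as rows, samples as columns); a tab-separated
#' manifest lists \code{file}, \code{condition_label} and
#' \code{source_label} per dataset.
#'
#' @param manifest_path path to the manifest TSV (datasets are resolved
#'   relative to it)
#' @return list of [expression_dataset()]s
#' @export
read_expression_datasets <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "condition_label") %in% names(man)))
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    mat <- as.matrix(utils::read.csv(file.path(dir, man$file[i]),
                                     row.names = 1L, check.names = FALSE))
    expression_dataset(mat, man$condition_label[i],
                       if ("source_label" %in% names(man))
                         man$source_label[i] else "")
  })
}

#' @rdname read_expression_datasets
#' @param datasets list of [expression_dataset()]s
#' @param dir output directory (created if needed)
#' @export
write_expression_datasets <- function(datasets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("dataset_%02d.csv", seq_along(datasets))
  for (i in seq_along(datasets)) {
    utils::write.csv(datasets[[i]]$mat, file.path(dir, files[i]))
  }
  man <- data.frame(file = files,
                    condition_label = vapply(datasets,
                                             function(d) d$condition_label,
                                             ""),
                    source_label = vapply(datasets,
                                          function(d) d$source_label, ""))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read an experimental outcome table
#'
#' Tab-separated table with columns \code{query} and \code{result}
#' (\code{supports-positive} / \code{supports-negative}).
#'
#' @param path file path
#' @return data.frame
#' @export
read_outcomes <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("query", "result") %in% names(out)))
  out
}

#' Bundled reconstruction of the naive-pluripotency network
#'
#' Loads the network definition shipped with the package
#' (\code{pluripotency_synthetic.net}). This is a \emph{synthetic
#' reconstruction}: the definite signalling axes (LIF activates Stat3, CH
#' inhibits Tcf3, PD inhibits MEK/ERK) and the published local topology
#' around Tfcp2l1 and Esrrb are encoded as reported, and the remaining
#' optional interactions were chosen once so that the bundled resetting
#' constraints are satisfiable. It is the worked example for the pipeline,
#' not the original study's supplementary model file.
#'
#' @return an [abn()]
#' @export
pluripotency_network <- function() {
  read_network(system.file("extdata", "pluripotency_synthetic.net",
                           package = "abnsynth", mustWork = TRUE))
}
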