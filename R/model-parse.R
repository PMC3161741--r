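#' Parse a plain-text food-web model file
#'
#' The model format has four sections introduced by the headers
#' `COMPARTMENTS`, `FLOWS`, `EQUALITIES` and `CONSTRAINTS`, an optional
#' `NAME <name>` line, and `#` comments. Compartment lines are
#' `id kind label...`; flow lines are `id: source -> target [role]`;
#' equality and constraint lines are linear expressions such as
#' `CgppTOph1 + CgppTOph2 + CgppTOph3 = 360.54` or
#' `CspgTOres - 0.2*Cph3TOspg <= 0`. Inequalities are stored canonically
#' with sense `>=` (a `<=` line is negated on input). Mass-balance
#' equalities are not written in the file; they are generated from the flow
#' topology, one per compartment.
#'
#' @param text model file content as a single string or character vector of
#'   lines.
#' @return a validated [fw_model()].
#' @seealso [read_model()], [write_model()]
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  name <- "model"
  section <- NA_character_
  comps <- list(); flows <- list(); eqs <- list(); ineqs <- list()
  for (ln in lines[nzchar(lines)]) {
    if (grepl("^NAME\\s+", ln)) { name <- sub("^NAME\\s+", "", ln); next }
    if (ln %in% c("COMPARTMENTS", "FLOWS", "EQUALITIES", "CONSTRAINTS")) {
      section <- ln; next
    }
    if (is.na(section))
      stop("line outside any section: '", ln, "'", call. = FALSE)
    if (section == "COMPARTMENTS") {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) < 2)
        stop("malformed compartment line: '", ln, "'", call. = FALSE)
      comps[[length(comps) + 1L]] <- data.frame(
        id = tok[1], kind = tok[2],
        label = if (length(tok) > 2) paste(tok[-(1:2)], collapse = " ")
                else tok[1])
    } else if (section == "FLOWS") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s*:\\s*(\\S+)\\s*->\\s*(\\S+)(\\s*\\[(\\w+)\\])?$", ln))[[1]]
      if (!length(m))
        stop("malformed flow line: '", ln, "'", call. = FALSE)
      flows[[length(flows) + 1L]] <- data.frame(
        id = m[2], source = m[3], target = m[4],
        role = if (nzchar(m[6])) m[6] else NA_character_)
    } else {
      con <- parse_linear_line(ln)
      if (con$sense == "=") {
        eqs[[length(eqs) + 1L]] <-
          linear_constraint(con$coefficients, con$rhs, "measurement",
                            note = ln)
      } else {
        sgn <- if (con$sense == ">=") 1 else -1
        ineqs[[length(ineqs) + 1L]] <-
          linear_constraint(sgn * con$coefficients, sgn * con$rhs,
                            note = ln)
      }
      if (section == "EQUALITIES" && con$sense != "=")
        stop("inequality in EQUALITIES section: '", ln, "'", call. = FALSE)
    }
  }
  fw_model(name,
           do.call(rbind, comps),
           do.call(rbind, flows),
           equalities = eqs, inequalities = ineqs)
}

# "0.45*a - 0.55*b + c >= 1.2" -> list(coefficients, sense, rhs)
parse_linear_line <- function(ln) {
  m <- regmatches(ln, regexec("^(.*?)(=|>=|<=)\\s*([-+0-9.eE]+)\\s*$", ln))[[1]]
  if (!length(m))
    stop("malformed constraint line: '", ln, "'", call. = FALSE)
  lhs <- m[2]; sense <- m[3]; rhs <- as.numeric(m[4])
  if (is.na(rhs))
    stop("malformed constraint rhs: '", ln, "'", call. = FALSE)
  # tokenize signed terms: [+-] [coef*] id
  lhs <- gsub("-", "+-", lhs, fixed = TRUE)
  terms <- trimws(strsplit(lhs, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  coefs <- numeric(0)
  for (tm in terms) {
    neg <- startsWith(tm, "-")
    tm <- trimws(sub("^-", "", tm))
    if (grepl("\\*", tm)) {
      parts <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
      cf <- as.numeric(parts[1]); id <- parts[2]
    } else if (grepl("^[0-9.]", tm)) {
      stop("constant term in constraint lhs: '", ln, "'", call. = FALSE)
    } else {
      cf <- 1; id <- tm
    }
    if (is.na(cf) || !nzchar(id))
      stop("malformed constraint term '", tm, "' in: '", ln, "'",
           call. = FALSE)
    if (neg) cf <- -cf
    coefs[id] <- (if (id %in% names(coefs)) coefs[[id]] else 0) + cf
  }
  list(coefficients = coefs, sense = sense, rhs = rhs)
}

#' @rdname parse_model
#' @param path path to a model file.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  parse_model(readLines(path, warn = FALSE))
}

#' Write a food-web model to its plain-text format
#'
#' Only measurement equalities and inequalities are written; mass balances
#' are regenerated from the topology on re-parse. `parse_model(write_model(spec))`
#' round-trips to an identical model.
#'
#' @param spec a `fw_model`.
#' @param path output file; `NULL` returns the lines invisibly instead.
#' @return the file lines, invisibly.
#' @export
write_model <- function(spec, path = NULL) {
  fmt_con <- function(con, sense) {
    cf <- con$coefficients
    terms <- vapply(seq_along(cf), function(i) {
      v <- abs(cf[[i]])
      term <- if (v == 1) names(cf)[i]
              else paste0(format(v, digits = 12), "*", names(cf)[i])
      paste0(if (cf[[i]] < 0) "- " else if (i > 1) "+ " else "", term)
    }, character(1))
    paste(paste(terms, collapse = " "), sense, format(con$rhs, digits = 12))
  }
  meas <- Filter(function(e) e$origin != "mass_balance", spec$equalities)
  lines <- c(
    paste("NAME", spec$name), "",
    "COMPARTMENTS",
    sprintf("%s %s %s", spec$compartments$id, spec$compartments$kind,
            spec$compartments$label),
    "", "FLOWS",
    sprintf("%s: %s -> %s [%s]", spec$flows$id, spec$flows$source,
            spec$flows$target, spec$flows$role),
    "", "EQUALITIES",
    vapply(meas, fmt_con, character(1), sense = "="),
    "", "CONSTRAINTS",
    vapply(spec$inequalities, fmt_con, character(1), sense = ">="))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read or write a flow vector as two-column CSV
#'
#' Format: columns `flow_id`, `value` (mg C m-2 d-1).
#'
#' @param path CSV path.
#' @param spec optional `fw_model`; when given, the vector is checked to key
#'   exactly the model's flows and is returned in flow declaration order.
#' @return named numeric vector of flow values.
#' @export
read_flows <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("flow file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("flow_id", "value") %in% names(df)) ||
      !is.numeric(df$value) || anyNA(df$value))
    stop("malformed flow CSV (need columns flow_id,value): ", path,
         call. = FALSE)
  x <- stats::setNames(df$value, df$flow_id)
  if (!is.null(spec)) x <- match_flows(spec, x)
  x
}

#' @rdname read_flows
#' @param x named numeric flow vector.
#' @export
write_flows <- function(x, path) {
  utils::write.csv(data.frame(flow_id = names(x), value = unname(x)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# reorder/validate a flow vector against a model's flow ids
match_flows <- function(spec, x) {
  miss <- setdiff(spec$flows$id, names(x))
  if (length(miss))
    stop("flow vector missing flow: ", miss[1], call. = FALSE)
  extra <- setdiff(names(x), spec$flows$id)
  if (length(extra))
    stop("flow vector has unknown flow: ", extra[1], call. = FALSE)
  x[spec$flows$id]
}
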