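#' Read a MEKA-style multi-label ARFF file
#'
#' Multi-label ARFF files follow the MEKA convention: the label attributes
#' come first and their number is declared in the relation name through a
#' `-C <q>` token (e.g. `@relation 'toy: -C 6'`). Dense and sparse
#' (`{index value, ...}`) data rows are both accepted; sparse rows are
#' densified. Label attributes must be binary (`{0,1}` nominal or numeric
#' 0/1); feature attributes must be numeric.
#'
#' @param path Path to the ARFF file.
#' @param label_count Number of leading label attributes, or `"auto"` to take
#'   it from the `-C` token in the relation name.
#' @return An `mld`.
#' @export
read_mld_arff <- function(path, label_count = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  parse_err <- function(line_no, msg) {
    stop(sprintf("ARFF parse error at line %d: %s", line_no, msg),
         call. = FALSE)
  }
  relation <- NULL
  attrs <- list()          # list of (name, type, levels)
  data_start <- NA_integer_
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (line == "" || startsWith(line, "%")) next
    low <- tolower(line)
    if (startsWith(low, "@relation")) {
      relation <- trimws(sub("(?i)^@relation", "", line, perl = TRUE))
      relation <- gsub("^['\"]|['\"]$", "", relation)
    } else if (startsWith(low, "@attribute")) {
      rest <- trimws(sub("(?i)^@attribute", "", line, perl = TRUE))
      if (startsWith(rest, "'") || startsWith(rest, "\"")) {
        qch <- substr(rest, 1, 1)
        close_at <- regexpr(qch, substr(rest, 2, nchar(rest)), fixed = TRUE)
        if (close_at < 0) parse_err(i, "unterminated quoted attribute name")
        nm <- substr(rest, 2, close_at)
        typ <- trimws(substr(rest, close_at + 2, nchar(rest)))
      } else {
        sp <- regexpr("[ \t]", rest)
        if (sp < 0) parse_err(i, "attribute declaration lacks a type")
        nm <- substr(rest, 1, sp - 1)
        typ <- trimws(substr(rest, sp + 1, nchar(rest)))
      }
      if (startsWith(typ, "{")) {
        lv <- trimws(strsplit(gsub("[{}]", "", typ), ",")[[1]])
        attrs[[length(attrs) + 1]] <- list(name = nm, type = "nominal",
                                           levels = lv)
      } else if (tolower(typ) %in% c("numeric", "real", "integer")) {
        attrs[[length(attrs) + 1]] <- list(name = nm, type = "numeric",
                                           levels = NULL)
      } else {
        parse_err(i, sprintf("unsupported attribute type '%s'", typ))
      }
    } else if (startsWith(low, "@data")) {
      data_start <- i + 1L
      break
    } else {
      parse_err(i, sprintf("unexpected token '%s'",
                           strsplit(line, "[ \t]")[[1]][1]))
    }
  }
  if (is.null(relation)) stop("ARFF file has no @relation header", call. = FALSE)
  if (is.na(data_start)) stop("ARFF file has no @data section", call. = FALSE)
  n_attr <- length(attrs)
  if (n_attr == 0) stop("ARFF file declares no attributes", call. = FALSE)

  if (identical(label_count, "auto")) {
    tok <- regmatches(relation, regexpr("-[Cc][ \t]+-?[0-9]+", relation))
    if (length(tok) == 0) {
      stop("label_count = \"auto\" but the relation name carries no -C token: ",
           relation, call. = FALSE)
    }
    label_count <- as.integer(sub("-[Cc][ \t]+", "", tok))
    if (label_count < 0) label_count <- abs(label_count)
  }
  label_count <- as.integer(label_count)
  if (label_count < 1 || label_count > n_attr) {
    stop("label_count must be between 1 and the number of attributes",
         call. = FALSE)
  }

  # label attributes must be binary
  for (j in seq_len(label_count)) {
    a <- attrs[[j]]
    ok <- (a$type == "numeric") ||
      (a$type == "nominal" && setequal(a$levels, c("0", "1")))
    if (!ok) {
      stop(sprintf("label attribute '%s' is not binary {0,1}", a$name),
           call. = FALSE)
    }
  }

  nominal_levels <- lapply(attrs, `[[`, "levels")
  mat <- matrix(NA_real_, nrow = 0, ncol = n_attr)
  rows <- list()
  ri <- 0L
  for (i in seq(data_start, length.out = max(0, length(raw) - data_start + 1))) {
    line <- trimws(raw[i])
    if (line == "" || startsWith(line, "%")) next
    if (startsWith(line, "{")) {             # sparse row: 0-based indices
      body <- trimws(gsub("^\\{|\\}$", "", line))
      vals <- rep(0, n_attr)
      if (body != "") {
        for (pair in trimws(strsplit(body, ",")[[1]])) {
          kv <- strsplit(pair, "[ \t]+")[[1]]
          if (length(kv) != 2) parse_err(i, "malformed sparse entry")
          idx <- suppressWarnings(as.integer(kv[1])) + 1L
          if (is.na(idx) || idx < 1 || idx > n_attr) {
            parse_err(i, "sparse index out of range")
          }
          vals[idx] <- arff_value(kv[2], nominal_levels[[idx]], i, attrs[[idx]]$name)
        }
      }
    } else {
      fields <- trimws(strsplit(line, ",")[[1]])
      if (length(fields) != n_attr) {
        parse_err(i, sprintf("expected %d fields, found %d",
                             n_attr, length(fields)))
      }
      vals <- vapply(seq_len(n_attr), function(j) {
        arff_value(fields[j], nominal_levels[[j]], i, attrs[[j]]$name)
      }, numeric(1))
    }
    ri <- ri + 1L
    rows[[ri]] <- vals
  }
  mat <- if (ri > 0) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = n_attr)
  nm <- vapply(attrs, `[[`, character(1), "name")
  colnames(mat) <- nm
  lab <- mat[, seq_len(label_count), drop = FALSE]
  if (length(lab) > 0 && !all(lab %in% c(0, 1))) {
    bad <- which(!(lab %in% c(0, 1)))[1]
    stop(sprintf("label attribute '%s' contains a non-binary value",
                 colnames(lab)[(bad - 1) %/% nrow(lab) + 1]), call. = FALSE)
  }
  feat <- mat[, setdiff(seq_len(n_attr), seq_len(label_count)), drop = FALSE]
  new_mld(feat, lab,
          label_names = nm[seq_len(label_count)],
          feature_names = colnames(feat) %||% character(0),
          provenance = path)
}

#' @keywords internal
arff_value <- function(x, levels, line_no, attr_name) {
  if (!is.null(levels)) {
    if (!(x %in% levels)) {
      stop(sprintf(
        "ARFF parse error at line %d: value '%s' not a declared level of '%s'",
        line_no, x, attr_name), call. = FALSE)
    }
    # binary nominals keep their face value; other nominals use level codes
    v <- suppressWarnings(as.numeric(x))
    return(if (is.na(v)) match(x, levels) - 1 else v)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop(sprintf(
      "ARFF parse error at line %d: non-numeric value '%s' for attribute '%s'",
      line_no, x, attr_name), call. = FALSE)
  }
  v
}

#' Write a multi-label dataset as MEKA-style ARFF
#'
#' Labels are written first as `{0,1}` nominal attributes and the relation
#' name carries the `-C <q>` token, so the file round-trips through
#' [read_mld_arff()] and is readable by MEKA.
#'
#' @param x An `mld`.
#' @param path Output file path.
#' @param relation Relation name; the `-C` token is appended automatically.
#' @return `path`, invisibly.
#' @export
write_mld_arff <- function(x, path, relation = "mld") {
  stopifnot(inherits(x, "mld"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("@relation '%s: -C %d'", relation, n_labels(x)), con)
  for (nm in x$label_names) {
    writeLines(sprintf("@attribute %s {0,1}", arff_quote(nm)), con)
  }
  for (nm in x$feature_names) {
    writeLines(sprintf("@attribute %s numeric", arff_quote(nm)), con)
  }
  writeLines("@data", con)
  if (n_instances(x) > 0) {
    body <- cbind(format(x$labels, trim = TRUE, scientific = FALSE),
                  format(x$features, trim = TRUE, digits = 17))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' @keywords internal
arff_quote <- function(nm) {
  if (grepl("[ ,{}%']", nm)) sprintf("'%s'", gsub("'", "\\\\'", nm)) else nm
}

#' Read a multi-label dataset from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param label_cols Character vector naming the binary label columns; the
#'   label matrix follows this order. All other numeric columns become
#'   features.
#' @return An `mld`.
#' @export
read_mld_csv <- function(path, label_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  mld(tibble::as_tibble(df), label_cols = label_cols, provenance = path)
}

#' Write a multi-label dataset as CSV
#'
#' @param x An `mld`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mld_csv <- function(x, path) {
  stopifnot(inherits(x, "mld"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(x$feature_names, x$label_names), collapse = ","), con)
  if (n_instances(x) > 0) {
    # %.17g guarantees a bit-exact numeric round-trip
    feat <- apply(x$features, 2, function(v) sprintf("%.17g", v))
    feat <- matrix(feat, nrow = n_instances(x))
    body <- cbind(feat, format(x$labels, trim = TRUE))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}
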