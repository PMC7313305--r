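# Turtle export / import of the knowledge base.
#
# The package owns one namespace (hw:) and borrows class names from the
# ICNP / SOSA / SSN / FOAF vocabularies (name-compatible only; the external
# ontology files are not loaded). The emitted dialect is deliberately
# restricted -- fully prefixed names, one triple per line -- which keeps the
# document valid Turtle while allowing an exact, diagnosable re-import.

TTL_PREFIXES <- c(
  hw   = "http://vitalwatch.example.org/ns#",
  icnp = "http://vitalwatch.example.org/vocab/icnp#",
  sosa = "http://www.w3.org/ns/sosa/",
  ssn  = "http://www.w3.org/ns/ssn/",
  foaf = "http://xmlns.com/foaf/0.1/",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

lit_str <- function(x) sprintf("\"%s\"", ttl_escape(as.character(x)))
lit_dbl <- function(x) sprintf("\"%s\"^^xsd:double", fmt_double(x))
lit_int <- function(x) sprintf("\"%d\"^^xsd:integer", as.integer(x))
lit_bool <- function(x) if (isTRUE(x)) "true" else "false"
lit_dt <- function(t) sprintf("\"%s\"^^xsd:dateTime", format_instant(t))

# allocate collision-free node names for raw identifiers
node_allocator <- function() {
  used <- new.env(parent = emptyenv())
  function(prefix, raw) {
    base <- paste0("hw:", prefix, gsub("[^A-Za-z0-9_]", "_", raw))
    name <- base; k <- 1
    while (!is.null(used[[name]]) && !identical(used[[name]], raw)) {
      k <- k + 1
      name <- paste0(base, "_", k)
    }
    used[[name]] <- raw
    name
  }
}

#' Export a knowledge base to Turtle
#'
#' @param kb knowledge base.
#' @param path optional file path; when `NULL` the document is returned as
#'   a character vector of lines.
#' @return lines invisibly (when `path` given) or visibly.
#' @export
export_turtle <- function(kb, path = NULL) {
  node <- node_allocator()
  L <- c(sprintf("@prefix %s: <%s> .", names(TTL_PREFIXES), TTL_PREFIXES), "")
  emit <- function(s, p, o) L[[length(L) + 1]] <<- paste(s, p, o, ".")

  emit("hw:kb", "a", "hw:KnowledgeBase")
  emit("hw:kb", "hw:exportVersion", lit_int(kb$version))

  for (code in names(kb$signs)) {
    d <- kb$signs[[code]]
    n <- node("sign_", code)
    emit(n, "a", "hw:VitalSignDefinition")
    emit(n, "hw:code", lit_str(d$code))
    emit(n, "hw:unit", lit_str(d$unit))
    emit(n, "hw:valueKind", lit_str(d$value_kind))
    if (!is.na(d$plausible_lower)) emit(n, "hw:plausibleLower",
                                        lit_dbl(d$plausible_lower))
    if (!is.na(d$plausible_upper)) emit(n, "hw:plausibleUpper",
                                        lit_dbl(d$plausible_upper))
  }

  pat_node <- function(id) node("patient_", id)
  for (id in names(kb$patients)) {
    p <- kb$patients[[id]]
    n <- pat_node(id)
    emit(n, "a", "icnp:Patient")
    emit(n, "a", "foaf:Person")
    emit(n, "hw:id", lit_str(id))
    if (!is.na(p$name)) emit(n, "foaf:name", lit_str(p$name))
    if (!is.na(p$birth_date)) emit(n, "hw:birthDate", lit_str(p$birth_date))
    if (!is.na(p$height_cm)) emit(n, "hw:heightCm", lit_dbl(p$height_cm))
    if (!is.na(p$weight_kg)) emit(n, "hw:weightKg", lit_dbl(p$weight_kg))
  }
  for (id in names(kb$platforms)) {
    pl <- kb$platforms[[id]]
    n <- node("platform_", id)
    emit(n, "a", "ssn:Platform")
    emit(n, "hw:id", lit_str(id))
    emit(pat_node(pl$owner), "hw:hasPlatform", n)
    emit(n, "hw:platformKind", lit_str(pl$kind))
    for (s in pl$sensor_ids) emit(n, "hw:hasSensor", lit_str(s))
  }

  for (cn in names(kb$axioms)) {
    ax <- kb$axioms[[cn]]
    n <- node("axiom_", cn)
    emit(n, "a", "hw:AbnormalRangeAxiom")
    emit(n, "hw:className", lit_str(ax$class_name))
    emit(n, "hw:onSign", lit_str(ax$sign_code))
    emit(n, "hw:provenance", lit_str(ax$provenance))
    emit(n, "hw:axiomVersion", lit_int(ax$version))
    emit(n, "hw:createdAt", lit_dt(ax$created_at))
    for (i in seq_len(nrow(ax$region))) {
      iv <- node("axiom_", paste0(cn, "_iv", i))
      emit(n, "hw:hasInterval", iv)
      emit(iv, "a", "hw:Interval")
      emit(iv, "hw:index", lit_int(i))
      emit(iv, "hw:lower", lit_dbl(ax$region$lower[i]))
      emit(iv, "hw:upper", lit_dbl(ax$region$upper[i]))
      emit(iv, "hw:lowerClosed", lit_bool(ax$region$lower_closed[i]))
      emit(iv, "hw:upperClosed", lit_bool(ax$region$upper_closed[i]))
    }
  }

  for (rid in names(kb$rules)) {
    r <- kb$rules[[rid]]
    n <- node("rule_", rid)
    emit(n, "a", "hw:ConjunctiveRule")
    emit(n, "hw:id", lit_str(rid))
    if (!is.na(r$label)) emit(n, "hw:label", lit_str(r$label))
    emit(n, "hw:provenance", lit_str(r$provenance))
    emit(n, "hw:enabled", lit_bool(r$enabled))
    emit(n, "hw:consequentType", lit_str(r$consequent$type))
    if (r$consequent$type == "assert_class") {
      emit(n, "hw:consequentClass", lit_str(r$consequent$class_name))
      emit(n, "hw:consequentVar", lit_str(r$consequent$var))
    } else {
      emit(n, "hw:consequentLabel", lit_str(r$consequent$label))
    }
    for (i in seq_along(r$antecedent)) {
      a <- r$antecedent[[i]]
      an <- node("rule_", paste0(rid, "_atom", i))
      emit(n, "hw:hasAtom", an)
      emit(an, "a", "hw:Atom")
      emit(an, "hw:index", lit_int(i))
      emit(an, "hw:atomKind", lit_str(a$kind))
      if (a$kind == "class") {
        emit(an, "hw:atomClass", lit_str(a$class_name))
        emit(an, "hw:atomVar", lit_str(a$var))
      } else if (a$kind == "property") {
        emit(an, "hw:atomProperty", lit_str(a$property))
        emit(an, "hw:atomSubject", lit_str(a$subject))
        emit(an, "hw:atomObject", lit_str(a$object))
      } else {
        emit(an, "hw:atomVar", lit_str(a$var))
        emit(an, "hw:atomOp", lit_str(a$op))
        emit(an, "hw:atomConst", lit_dbl(a$const))
      }
    }
  }

  # observations and alerts are emitted vectorized: streams dominate the
  # document size and per-triple appends would not scale
  pat_nodes <- vapply(names(kb$patients), pat_node, "")
  sign_nodes <- vapply(names(kb$signs), function(s) node("sign_", s), "")
  obs <- kb$observations
  obs_lines <- character()
  if (nrow(obs) > 0) {
    n <- make.unique(paste0("hw:obs_",
                            gsub("[^A-Za-z0-9_]", "_", obs$observation_id)),
                     sep = "_")
    rn <- paste0(n, "_result")
    blocks <- c(
      paste(n, "a sosa:Observation ."),
      paste(n, "hw:id", vapply(obs$observation_id, lit_str, ""), "."),
      paste(n, "hw:ofPatient", pat_nodes[obs$patient_id], "."),
      paste(n, "sosa:observedProperty", sign_nodes[obs$sign_code], "."),
      paste(n, "sosa:resultTime", lit_dt(obs$timestamp), "."),
      ifelse(is.na(obs$sensor_id), NA, paste(
        n, "sosa:madeBySensor",
        vapply(as.character(obs$sensor_id), lit_str, ""), ".")),
      paste(n, "sosa:hasResult", rn, "."),
      paste(rn, "a icnp:Result ."),
      ifelse(is.na(obs$value), NA,
             paste(rn, "hw:numericValue", lit_dbl(obs$value), ".")),
      ifelse(is.na(obs$value_nominal), NA, paste(
        rn, "hw:nominalValue",
        vapply(as.character(obs$value_nominal), lit_str, ""), ".")))
    obs_lines <- blocks[!is.na(blocks)]
  }

  al <- kb$alerts
  al_lines <- character()
  if (nrow(al) > 0) {
    n <- make.unique(paste0("hw:alert_",
                            gsub("[^A-Za-z0-9_]", "_", al$alert_id)),
                     sep = "_")
    ev_n <- lengths(al$evidence)
    al_lines <- c(
      paste(n, "a hw:Alert ."),
      paste(n, "hw:id", vapply(al$alert_id, lit_str, ""), "."),
      paste(n, "hw:ofPatient", pat_nodes[al$patient_id], "."),
      paste(n, "hw:alertTime", lit_dt(al$timestamp), "."),
      paste(n, "hw:label", vapply(al$label, lit_str, ""), "."),
      paste(n, "hw:firedRule", vapply(al$rule_id, lit_str, ""), "."),
      if (sum(ev_n) > 0)
        paste(rep(n, ev_n), "hw:evidence",
              vapply(unlist(al$evidence), lit_str, ""), "."))
  }

  lines <- c(unlist(L), obs_lines, al_lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- parsing ---------------------------------------------------------------

TTL_TOKEN_RE <- paste0(
  '"(?:[^"\\\\]|\\\\.)*"',                       # quoted literal
  '(?:\\^\\^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z_][A-Za-z0-9_.-]*)?', # ^^datatype
  "|\\S+")

parse_turtle_triples <- function(lines) {
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "@prefix")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(s = character(), p = character(), o = character(),
                      kind = character(), stringsAsFactors = FALSE))
  toks <- regmatches(lines, gregexpr(TTL_TOKEN_RE, lines, perl = TRUE))
  bad <- vapply(toks, function(t) length(t) != 4 || t[4] != ".", logical(1))
  if (any(bad))
    vw_stop("turtle parse error at line %d: expected 'subject predicate object .', got: %s",
            line_no[bad][1], lines[bad][1])
  m <- matrix(unlist(toks), ncol = 4, byrow = TRUE)
  subj <- m[, 1]
  pred <- ifelse(m[, 2] == "a", "rdf:type", m[, 2])
  obj <- m[, 3]
  is_lit <- startsWith(obj, "\"")
  is_bool <- !is_lit & obj %in% c("true", "false")
  is_iri <- !is_lit & !is_bool & grepl("^[A-Za-z][A-Za-z0-9_.-]*:\\S+$", obj)
  unrec <- !is_lit & !is_bool & !is_iri
  if (any(unrec))
    vw_stop("turtle parse error at line %d: unrecognized object '%s'",
            line_no[unrec][1], obj[unrec][1])
  o <- obj
  kind <- ifelse(is_bool, "literal:xsd:boolean", ifelse(is_iri, "iri", ""))
  if (any(is_lit)) {
    body <- sub('\\^\\^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z_][A-Za-z0-9_.-]*$', "",
                obj[is_lit])
    dt <- ifelse(nchar(body) < nchar(obj[is_lit]),
                 sub("^.*\\^\\^", "", obj[is_lit]), "")
    o[is_lit] <- ttl_unescape(substr(body, 2, nchar(body) - 1))
    kind[is_lit] <- paste0("literal:", dt)
  }
  data.frame(s = subj, p = pred, o = o, kind = kind,
             stringsAsFactors = FALSE)
}

#' Import a knowledge base from Turtle
#'
#' Inverse of [export_turtle()]: `import_turtle(export_turtle(kb))` is
#' structurally equal to `kb` (version counters and ordering excluded; see
#' [kb_equal()]). Unknown predicates in the hw: namespace and malformed
#' lines raise parse errors with line diagnostics.
#'
#' @param x character vector of Turtle lines, a single string, or a path to
#'   a `.ttl` file.
#' @return a `vw_kb`.
#' @export
import_turtle <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x <- readLines(x)
  if (length(x) == 1) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  tr <- parse_turtle_triples(x)
  # hashed subject index; named-list lookup would be linear per subject
  by_subject <- list2env(split(seq_len(nrow(tr)), tr$s), hash = TRUE,
                         parent = emptyenv())

  objs_of <- function(s, p) {
    i <- by_subject[[s]]
    tr$o[i][tr$p[i] == p]
  }
  # vectorized subject -> object map for one predicate (first triple wins)
  get_many <- function(subjects, p) {
    sel <- tr$p == p
    unname(stats::setNames(tr$o[sel], tr$s[sel])[subjects])
  }
  obj1 <- function(s, p, default = NA_character_) {
    v <- objs_of(s, p)
    if (length(v) == 0) default else v[1]
  }
  num1 <- function(s, p, default = NA_real_) {
    v <- obj1(s, p)
    if (is.na(v)) default else parse_double(v)
  }
  subjects_of_type <- function(type) unique(tr$s[tr$p == "rdf:type" &
                                                   tr$o == type])
  known <- c("hw:KnowledgeBase", "hw:VitalSignDefinition", "icnp:Patient",
             "foaf:Person", "ssn:Platform", "hw:AbnormalRangeAxiom",
             "hw:Interval", "hw:ConjunctiveRule", "hw:Atom",
             "sosa:Observation", "icnp:Result", "hw:Alert")
  unk <- setdiff(unique(tr$o[tr$p == "rdf:type"]), known)
  if (length(unk)) vw_stop("unknown class in document: %s", unk[1])

  # sign catalog first (observations refer to it)
  signs <- list()
  for (s in subjects_of_type("hw:VitalSignDefinition")) {
    d <- vital_sign(obj1(s, "hw:code"), obj1(s, "hw:unit", ""),
                    obj1(s, "hw:valueKind", "real"),
                    num1(s, "hw:plausibleLower"), num1(s, "hw:plausibleUpper"))
    signs[[d$code]] <- d
  }
  kb <- kb_new(sign_catalog = signs[order(names(signs))])

  raw_id <- function(s) obj1(s, "hw:id")
  pat_subjects <- subjects_of_type("icnp:Patient")
  pat_ids <- vapply(pat_subjects, raw_id, "", USE.NAMES = FALSE)
  for (i in order(pat_ids)) {
    s <- pat_subjects[i]
    kb <- kb_add_patient(kb, pat_ids[i], name = obj1(s, "foaf:name"),
                         birth_date = obj1(s, "hw:birthDate"),
                         height_cm = num1(s, "hw:heightCm"),
                         weight_kg = num1(s, "hw:weightKg"))
  }
  pat_of_node <- stats::setNames(pat_ids, pat_subjects)

  pl_subjects <- subjects_of_type("ssn:Platform")
  pl_ids <- vapply(pl_subjects, raw_id, "", USE.NAMES = FALSE)
  for (i in order(pl_ids)) {
    s <- pl_subjects[i]
    owner_node <- tr$s[tr$p == "hw:hasPlatform" & tr$o == s][1]
    kb <- kb_add_platform(kb, pl_ids[i], pat_of_node[[owner_node]],
                          obj1(s, "hw:platformKind", "body"),
                          sort(objs_of(s, "hw:hasSensor")))
  }

  for (s in sort(subjects_of_type("hw:AbnormalRangeAxiom"))) {
    iv_nodes <- objs_of(s, "hw:hasInterval")
    iv_nodes <- iv_nodes[order(vapply(iv_nodes, function(n)
      as.integer(obj1(n, "hw:index", "1")), integer(1)))]
    region <- interval_set(
      lower = vapply(iv_nodes, function(n) num1(n, "hw:lower"), 0),
      upper = vapply(iv_nodes, function(n) num1(n, "hw:upper"), 0),
      lower_closed = vapply(iv_nodes, function(n)
        obj1(n, "hw:lowerClosed", "false") == "true", logical(1)),
      upper_closed = vapply(iv_nodes, function(n)
        obj1(n, "hw:upperClosed", "false") == "true", logical(1)))
    ax <- abnormal_range_axiom(obj1(s, "hw:className"), obj1(s, "hw:onSign"),
                               region, obj1(s, "hw:provenance", "manual"),
                               version = as.integer(obj1(s, "hw:axiomVersion", "1")),
                               created_at = obj1(s, "hw:createdAt"))
    kb$axioms[[ax$class_name]] <- ax
  }

  for (s in sort(subjects_of_type("hw:ConjunctiveRule"))) {
    atom_nodes <- objs_of(s, "hw:hasAtom")
    atom_nodes <- atom_nodes[order(vapply(atom_nodes, function(n)
      as.integer(obj1(n, "hw:index", "1")), integer(1)))]
    atoms <- lapply(atom_nodes, function(n) {
      switch(obj1(n, "hw:atomKind"),
        class = atom_class(obj1(n, "hw:atomClass"), obj1(n, "hw:atomVar")),
        property = atom_property(obj1(n, "hw:atomProperty"),
                                 obj1(n, "hw:atomSubject"),
                                 obj1(n, "hw:atomObject")),
        comparison = atom_comparison(obj1(n, "hw:atomVar"),
                                     obj1(n, "hw:atomOp"),
                                     num1(n, "hw:atomConst")),
        vw_stop("unknown atom kind on node %s", n))
    })
    cons <- if (obj1(s, "hw:consequentType") == "assert_class") {
      consequent_assert_class(obj1(s, "hw:consequentClass"),
                              obj1(s, "hw:consequentVar"))
    } else {
      consequent_emit_alert(obj1(s, "hw:consequentLabel"))
    }
    rule <- conjunctive_rule(raw_id(s), atoms, cons,
                             label = obj1(s, "hw:label"),
                             provenance = obj1(s, "hw:provenance", "manual"),
                             enabled = obj1(s, "hw:enabled", "true") == "true")
    kb$rules[[rule$rule_id]] <- rule
  }

  obs_subjects <- subjects_of_type("sosa:Observation")
  if (length(obs_subjects)) {
    ids <- get_many(obs_subjects, "hw:id")
    ord <- order(ids)
    subj <- obs_subjects[ord]
    rn <- get_many(subj, "sosa:hasResult")
    sign_nodes <- get_many(subj, "sosa:observedProperty")
    sign_code <- get_many(sign_nodes, "hw:code")
    nv <- get_many(rn, "hw:numericValue")
    num <- rep(NA_real_, length(nv))
    num[!is.na(nv)] <- parse_double(nv[!is.na(nv)])
    df <- data.frame(
      observation_id = ids[ord],
      patient_id = unname(pat_of_node[get_many(subj, "hw:ofPatient")]),
      sign_code = sign_code,
      timestamp = parse_instant(get_many(subj, "sosa:resultTime")),
      value = num,
      value_nominal = get_many(rn, "hw:nominalValue"),
      sensor_id = get_many(subj, "sosa:madeBySensor"),
      stringsAsFactors = FALSE)
    kb$observations <- rbind(kb$observations, df)
    kb <- kb_bump(kb, sprintf("import %d observations", nrow(df)))
  }

  al_subjects <- subjects_of_type("hw:Alert")
  if (length(al_subjects)) {
    ids <- get_many(al_subjects, "hw:id")
    subj <- al_subjects[order(ids)]
    df <- data.frame(
      alert_id = ids[order(ids)],
      patient_id = unname(pat_of_node[get_many(subj, "hw:ofPatient")]),
      timestamp = parse_instant(get_many(subj, "hw:alertTime")),
      label = get_many(subj, "hw:label"),
      rule_id = get_many(subj, "hw:firedRule"),
      stringsAsFactors = FALSE)
    df$evidence <- lapply(subj, function(s) sort(objs_of(s, "hw:evidence")))
    kb$alerts <- rbind(kb$alerts, df)
    kb <- kb_bump(kb, sprintf("import %d alerts", length(al_subjects)))
  }
  kb
}

# ---- structural equality ---------------------------------------------------

canon_kb <- function(kb) {
  obs <- kb$observations[order(kb$observations$observation_id), , drop = FALSE]
  obs$timestamp <- format_instant(obs$timestamp)
  rownames(obs) <- NULL
  al <- kb$alerts[order(kb$alerts$alert_id), , drop = FALSE]
  al$timestamp <- format_instant(al$timestamp)
  al$evidence <- lapply(al$evidence, function(e) sort(as.character(e)))
  rownames(al) <- NULL
  list(
    signs = lapply(kb$signs[sort(names(kb$signs))], unclass),
    patients = lapply(kb$patients[sort(names(kb$patients))], function(p) {
      p$platform_ids <- sort(p$platform_ids); p
    }),
    platforms = lapply(kb$platforms[sort(names(kb$platforms))], function(pl) {
      pl$sensor_ids <- sort(pl$sensor_ids); pl
    }),
    axioms = lapply(kb$axioms[sort(names(kb$axioms))], function(ax) {
      list(class_name = ax$class_name, sign_code = ax$sign_code,
           region = as.data.frame(interval_normalize(ax$region)),
           provenance = ax$provenance, version = as.integer(ax$version),
           created_at = format_instant(ax$created_at))
    }),
    rules = lapply(kb$rules[sort(names(kb$rules))], rule_to_list),
    observations = obs, alerts = al
  )
}

#' Structural equality of two knowledge bases
#'
#' Compares patients, platforms, sign catalog, axioms, rules, observations
#' and alerts, ignoring version counters, insertion order and derived
#' (re-computable) class assertions.
#'
#' @param a,b knowledge bases.
#' @return logical.
#' @export
kb_equal <- function(a, b) identical(canon_kb(a), canon_kb(b))
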