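#' @include AllClasses.R
NULL

.dvBaseIRI <- "http://example.org/dermvis"

emptyAxioms <- function() {
  data.frame(kind = character(0), subject = character(0),
              property = character(0), object = character(0),
              value = integer(0), stringsAsFactors = FALSE)
}

emptyEntities <- function() {
  data.frame(label = character(0), type = character(0),
             prefLabel = character(0), altLabels = character(0),
             stringsAsFactors = FALSE)
}

#' Create an empty ontology model
#'
#' @param iri ontology IRI; entity IRIs are `<iri>#<CamelCaseLabel>`.
#' @param label ontology label.
#' @return an [OntologyModel].
#' @export
ontologyModel <- function(iri = .dvBaseIRI, label = "ontology") {
  new("OntologyModel", iri = iri, label = label, entities = emptyEntities(),
      axioms = emptyAxioms(), imports = list())
}

#' Declare an entity
#'
#' Every entity has exactly one SKOS preferred label (defaulting to the
#' lower-cased, space-separated form of its CamelCase label) and any number
#' of alternative labels. Unnamed entities are rejected.
#'
#' @param model an [OntologyModel].
#' @param label CamelCase entity label (becomes the IRI fragment).
#' @param type `"class"`, `"objectProperty"`, `"dataProperty"` or
#'   `"individual"`.
#' @param prefLabel SKOS preferred label.
#' @param altLabels SKOS alternative labels.
#' @return the updated model.
#' @export
addEntity <- function(model, label, type = "class",
                      prefLabel = labelWords(label),
                      altLabels = character(0)) {
  if (is.na(label) || !nzchar(label))
    dvStop("cannot declare an unnamed entity", "unnamedEntityError")
  if (any(model@entities$label == label & model@entities$type == type))
    return(model)
  model@entities <- rbind(model@entities, data.frame(
    label = label, type = type, prefLabel = prefLabel,
    altLabels = paste(altLabels, collapse = "|"),
    stringsAsFactors = FALSE))
  model
}

#' Add an axiom
#'
#' Axioms are stored as rows of a canonical table and deduplicated; the
#' table is re-sorted lexicographically at export so that serialization is
#' deterministic.
#'
#' @param model an [OntologyModel].
#' @param kind axiom kind (e.g. `"SubClassOf"`, `"ObjectExactCardinality"`,
#'   `"ObjectSomeValuesFrom"`, `"InverseObjectProperties"`,
#'   `"DataPropertyRange"`).
#' @param subject,property,object entity labels as applicable.
#' @param value integer qualifier (cardinality).
#' @return the updated model.
#' @export
addAxiom <- function(model, kind, subject, property = NA, object = NA,
                     value = NA) {
  row <- data.frame(kind = kind, subject = subject,
                    property = as.character(property),
                    object = as.character(object),
                    value = as.integer(value), stringsAsFactors = FALSE)
  ax <- rbind(model@axioms, row)
  model@axioms <- unique(ax)
  model
}

canonicalAxioms <- function(ax) {
  if (!nrow(ax)) return(ax)
  key <- do.call(paste, c(lapply(ax, function(col) {
    ifelse(is.na(col), "", as.character(col))
  }), sep = "\r"))
  out <- ax[order(key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

canonicalEntities <- function(e) {
  out <- e[order(e$type, e$label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count declared entities
#'
#' @param model an [OntologyModel].
#' @param includeImports also count entities declared by the import
#'   closure (shared declarations counted once).
#' @return named integer vector: `classes`, `objectProperties`,
#'   `dataProperties`.
#' @export
entityCounts <- function(model, includeImports = FALSE) {
  collect <- function(m) {
    e <- m@entities
    if (includeImports)
      for (im in m@imports) e <- rbind(e, collect(im))
    e
  }
  e <- unique(collect(model)[c("label", "type")])
  c(classes = sum(e$type == "class"),
    objectProperties = sum(e$type == "objectProperty"),
    dataProperties = sum(e$type == "dataProperty"))
}

setMethod("show", "OntologyModel", function(object) {
  ct <- entityCounts(object)
  cat(sprintf(
    "OntologyModel <%s>: %d classes, %d object properties, %d data properties, %d axioms%s\n",
    object@iri, ct["classes"], ct["objectProperties"], ct["dataProperties"],
    nrow(object@axioms),
    if (length(object@imports))
      sprintf(" (+%d import(s))", length(object@imports)) else ""))
})

#' Are two models axiom-equivalent?
#'
#' Equivalence compares the canonicalized axiom tables, entity declarations
#' and labels; import lists are compared by IRI.
#'
#' @param a,b [OntologyModel] objects.
#' @return logical.
#' @export
axiomEquivalent <- function(a, b) {
  isTRUE(all.equal(canonicalAxioms(a@axioms), canonicalAxioms(b@axioms))) &&
    isTRUE(all.equal(canonicalEntities(a@entities),
                     canonicalEntities(b@entities))) &&
    identical(sort(vapply(a@imports, function(m) m@iri, character(1))),
              sort(vapply(b@imports, function(m) m@iri, character(1))))
}

#' Diff two ontology models
#' @param a,b [OntologyModel] objects.
#' @return list with `axiomsOnlyInA`, `axiomsOnlyInB`, `entitiesOnlyInA`,
#'   `entitiesOnlyInB` data.frames.
#' @export
owlDiff <- function(a, b) {
  axKey <- function(ax) do.call(paste, c(ax, sep = "\r"))
  ea <- canonicalEntities(a@entities); eb <- canonicalEntities(b@entities)
  aa <- canonicalAxioms(a@axioms); ab <- canonicalAxioms(b@axioms)
  list(axiomsOnlyInA = aa[!axKey(aa) %in% axKey(ab), , drop = FALSE],
       axiomsOnlyInB = ab[!axKey(ab) %in% axKey(aa), , drop = FALSE],
       entitiesOnlyInA = ea[!ea$label %in% eb$label, , drop = FALSE],
       entitiesOnlyInB = eb[!eb$label %in% ea$label, , drop = FALSE])
}

## ---- serialization ----

.prefixes <- c(
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  skos = "http://www.w3.org/2004/02/skos/core#")

.typeClass <- c(class = "owl:Class", objectProperty = "owl:ObjectProperty",
                dataProperty = "owl:DatatypeProperty",
                individual = "owl:NamedIndividual")

ttlLit <- function(x) sprintf('"%s"', gsub('"', '\\\\"', x))

restrictionTTL <- function(row) {
  onProp <- sprintf(":%s", row$property)
  switch(row$kind,
    ObjectExactCardinality = sprintf(
      paste0("[ rdf:type owl:Restriction ; owl:onProperty %s ; ",
             "owl:qualifiedCardinality \"%d\"^^xsd:nonNegativeInteger ; ",
             "owl:onClass :%s ]"), onProp, row$value, row$object),
    ObjectMaxCardinality = sprintf(
      paste0("[ rdf:type owl:Restriction ; owl:onProperty %s ; ",
             "owl:maxQualifiedCardinality \"%d\"^^xsd:nonNegativeInteger ; ",
             "owl:onClass :%s ]"), onProp, row$value, row$object),
    ObjectSomeValuesFrom = sprintf(
      paste0("[ rdf:type owl:Restriction ; owl:onProperty %s ; ",
             "owl:someValuesFrom :%s ]"), onProp, row$object))
}

#' Export a model as OWL2 text
#'
#' Writes the model in Turtle or RDF/XML with SKOS preferred/alternative
#' labels. Entities and axioms are emitted in canonical lexicographic
#' order, so exporting, importing and exporting again yields byte-identical
#' text. Polygon point counts are encoded as exact qualified-cardinality
#' restrictions, and data-property ranges are typed (`xsd:integer`,
#' `xsd:string`), never plain literals.
#'
#' @param model an [OntologyModel] (validated).
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @param path optional output file.
#' @return the document text (invisibly when written to `path`).
#' @export
exportOWL <- function(model, dialect = c("turtle", "rdfxml"), path = NULL) {
  dialect <- match.arg(dialect)
  validObject(model)
  if (any(!nzchar(model@entities$label)))
    dvStop("cannot export an unnamed entity", "unnamedEntityError")
  txt <- if (dialect == "turtle") exportTurtle(model) else exportRDFXML(model)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

exportTurtle <- function(model) {
  e <- canonicalEntities(model@entities)
  ax <- canonicalAxioms(model@axioms)
  out <- c(sprintf("@prefix : <%s#> .", model@iri),
           sprintf("@prefix %s: <%s> .", names(.prefixes), .prefixes),
           "",
           sprintf("<%s> rdf:type owl:Ontology ;", model@iri),
           sprintf("    rdfs:label %s%s", ttlLit(model@label),
                   if (length(model@imports)) " ;" else " ."))
  if (length(model@imports)) {
    iris <- sort(vapply(model@imports, function(m) m@iri, character(1)))
    out <- c(out, sprintf("    owl:imports <%s>%s", iris,
                          c(rep(" ;", length(iris) - 1), " .")))
  }
  for (i in seq_len(nrow(e))) {
    row <- e[i, ]
    lines <- c(sprintf(":%s rdf:type %s ;", row$label,
                       .typeClass[[row$type]]),
               sprintf("    skos:prefLabel %s", ttlLit(row$prefLabel)))
    alts <- strsplit(row$altLabels, "|", fixed = TRUE)[[1]]
    alts <- alts[nzchar(alts)]
    for (al in sort(alts))
      lines <- c(lines, sprintf("    skos:altLabel %s", ttlLit(al)))
    sub <- ax[ax$subject == row$label & row$type == "class" &
                ax$kind %in% c("SubClassOf", "ObjectExactCardinality",
                               "ObjectMaxCardinality",
                               "ObjectSomeValuesFrom"), , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      r <- sub[j, ]
      rhs <- if (r$kind == "SubClassOf") sprintf(":%s", r$object)
             else restrictionTTL(r)
      lines <- c(lines, sprintf("    rdfs:subClassOf %s", rhs))
    }
    if (row$type == "objectProperty") {
      prow <- ax[ax$kind == "InverseObjectProperties" &
                   ax$subject == row$label, , drop = FALSE]
      for (j in seq_len(nrow(prow)))
        lines <- c(lines, sprintf("    owl:inverseOf :%s", prow$object[j]))
      prow <- ax[ax$kind == "SubObjectPropertyOf" &
                   ax$subject == row$label, , drop = FALSE]
      for (j in seq_len(nrow(prow)))
        lines <- c(lines, sprintf("    rdfs:subPropertyOf :%s",
                                  prow$object[j]))
      for (kind in c("ObjectPropertyDomain", "ObjectPropertyRange")) {
        prow <- ax[ax$kind == kind & ax$subject == row$label, , drop = FALSE]
        for (j in seq_len(nrow(prow)))
          lines <- c(lines, sprintf("    %s :%s",
                                    if (kind == "ObjectPropertyDomain")
                                      "rdfs:domain" else "rdfs:range",
                                    prow$object[j]))
      }
      if (any(ax$kind == "FunctionalObjectProperty" &
                ax$subject == row$label))
        lines <- c(lines, "    rdf:type owl:FunctionalProperty")
    }
    if (row$type == "dataProperty") {
      prow <- ax[ax$kind == "DataPropertyDomain" &
                   ax$subject == row$label, , drop = FALSE]
      for (j in seq_len(nrow(prow)))
        lines <- c(lines, sprintf("    rdfs:domain :%s", prow$object[j]))
      prow <- ax[ax$kind == "DataPropertyRange" &
                   ax$subject == row$label, , drop = FALSE]
      for (j in seq_len(nrow(prow)))
        lines <- c(lines, sprintf("    rdfs:range xsd:%s", prow$object[j]))
    }
    n <- length(lines)
    lines[-n] <- paste0(lines[-n], "")
    lines[seq_len(n - 1)][-1] <- lines[seq_len(n - 1)][-1]
    body <- paste0(lines, c(rep(" ;", n - 1), " ."))
    # first line already ends with ';'
    body[1] <- lines[1]
    out <- c(out, "", body)
  }
  dis <- ax[ax$kind == "DisjointClasses", , drop = FALSE]
  for (j in seq_len(nrow(dis)))
    out <- c(out, "", sprintf(":%s owl:disjointWith :%s .",
                              dis$subject[j], dis$object[j]))
  paste(c(out, ""), collapse = "\n")
}

exportRDFXML <- function(model) {
  e <- canonicalEntities(model@entities)
  ax <- canonicalAxioms(model@axioms)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ref <- function(lbl) sprintf("%s#%s", model@iri, lbl)
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf('<rdf:RDF xmlns="%s#"', model@iri),
           sprintf('    xmlns:%s="%s"', names(.prefixes), .prefixes),
           sprintf('    xml:base="%s">', model@iri),
           sprintf('  <owl:Ontology rdf:about="%s">', model@iri),
           sprintf('    <rdfs:label>%s</rdfs:label>', esc(model@label)))
  if (length(model@imports)) {
    iris <- sort(vapply(model@imports, function(m) m@iri, character(1)))
    out <- c(out, sprintf('    <owl:imports rdf:resource="%s"/>', iris))
  }
  out <- c(out, "  </owl:Ontology>")
  tags <- c(class = "owl:Class", objectProperty = "owl:ObjectProperty",
            dataProperty = "owl:DatatypeProperty",
            individual = "owl:NamedIndividual")
  for (i in seq_len(nrow(e))) {
    row <- e[i, ]
    tag <- tags[[row$type]]
    out <- c(out, sprintf('  <%s rdf:about="%s">', tag, ref(row$label)),
             sprintf('    <skos:prefLabel>%s</skos:prefLabel>',
                     esc(row$prefLabel)))
    alts <- strsplit(row$altLabels, "|", fixed = TRUE)[[1]]
    for (al in sort(alts[nzchar(alts)]))
      out <- c(out, sprintf('    <skos:altLabel>%s</skos:altLabel>',
                            esc(al)))
    if (row$type == "class") {
      sub <- ax[ax$subject == row$label &
                  ax$kind %in% c("SubClassOf", "ObjectExactCardinality",
                                 "ObjectMaxCardinality",
                                 "ObjectSomeValuesFrom"), , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        r <- sub[j, ]
        if (r$kind == "SubClassOf") {
          out <- c(out, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>',
                                ref(r$object)))
        } else {
          card <- switch(r$kind,
            ObjectExactCardinality = sprintf(
              paste0('        <owl:qualifiedCardinality ',
                     'rdf:datatype="%snonNegativeInteger">%d',
                     '</owl:qualifiedCardinality>'),
              .prefixes[["xsd"]], r$value),
            ObjectMaxCardinality = sprintf(
              paste0('        <owl:maxQualifiedCardinality ',
                     'rdf:datatype="%snonNegativeInteger">%d',
                     '</owl:maxQualifiedCardinality>'),
              .prefixes[["xsd"]], r$value),
            ObjectSomeValuesFrom = sprintf(
              '        <owl:someValuesFrom rdf:resource="%s"/>',
              ref(r$object)))
          onClass <- if (r$kind != "ObjectSomeValuesFrom")
            sprintf('        <owl:onClass rdf:resource="%s"/>',
                    ref(r$object)) else NULL
          out <- c(out, "    <rdfs:subClassOf>",
                   "      <owl:Restriction>",
                   sprintf('        <owl:onProperty rdf:resource="%s"/>',
                           ref(r$property)),
                   card, onClass,
                   "      </owl:Restriction>", "    </rdfs:subClassOf>")
        }
      }
      dis <- ax[ax$kind == "DisjointClasses" & ax$subject == row$label, ,
                drop = FALSE]
      for (j in seq_len(nrow(dis)))
        out <- c(out, sprintf('    <owl:disjointWith rdf:resource="%s"/>',
                              ref(dis$object[j])))
    } else if (row$type == "objectProperty") {
      for (spec in list(c("InverseObjectProperties", "owl:inverseOf"),
                        c("SubObjectPropertyOf", "rdfs:subPropertyOf"),
                        c("ObjectPropertyDomain", "rdfs:domain"),
                        c("ObjectPropertyRange", "rdfs:range"))) {
        prow <- ax[ax$kind == spec[1] & ax$subject == row$label, ,
                   drop = FALSE]
        for (j in seq_len(nrow(prow)))
          out <- c(out, sprintf('    <%s rdf:resource="%s"/>', spec[2],
                                ref(prow$object[j])))
      }
      if (any(ax$kind == "FunctionalObjectProperty" &
                ax$subject == row$label))
        out <- c(out, paste0('    <rdf:type rdf:resource="',
                             .prefixes[["owl"]], 'FunctionalProperty"/>'))
    } else if (row$type == "dataProperty") {
      prow <- ax[ax$kind == "DataPropertyDomain" & ax$subject == row$label, ,
                 drop = FALSE]
      for (j in seq_len(nrow(prow)))
        out <- c(out, sprintf('    <rdfs:domain rdf:resource="%s"/>',
                              ref(prow$object[j])))
      prow <- ax[ax$kind == "DataPropertyRange" & ax$subject == row$label, ,
                 drop = FALSE]
      for (j in seq_len(nrow(prow)))
        out <- c(out, sprintf('    <rdfs:range rdf:resource="%s%s"/>',
                              .prefixes[["xsd"]], prow$object[j]))
    }
    out <- c(out, sprintf("  </%s>", tag))
  }
  paste(c(out, "</rdf:RDF>", ""), collapse = "\n")
}

## ---- import ----

stripIRI <- function(x) sub("^.*[#/]", "", x)

#' Import an OWL2 document
#'
#' Parses Turtle or RDF/XML (auto-detected) back into an [OntologyModel].
#' The Turtle reader handles the canonical subset this package emits plus
#' simple hand-written toys; RDF/XML is parsed with a full XML parser.
#' Unrecognized Turtle statements are preserved as opaque annotation
#' axioms; malformed documents raise an error with the offending location.
#'
#' @param path file path or literal document text.
#' @param dialect `"auto"`, `"turtle"` or `"rdfxml"`.
#' @return an [OntologyModel] (imports recorded by IRI only).
#' @export
importOWL <- function(path, dialect = "auto") {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", txt)) "rdfxml"
               else "turtle"
  }
  if (dialect == "rdfxml") importRDFXML(txt) else importTurtle(txt)
}

importRDFXML <- function(txt) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(txt)),
                  error = function(e) {
    dvStop(sprintf("RDF/XML parse failure: %s", conditionMessage(e)),
           "parseError")
  })
  ns <- c(owl = .prefixes[["owl"]], rdf = .prefixes[["rdf"]],
          rdfs = .prefixes[["rdfs"]], skos = .prefixes[["skos"]])
  ont <- xml2::xml_find_first(doc, ".//owl:Ontology", ns)
  iri <- xml2::xml_attr(ont, "about")
  label <- xml2::xml_text(xml2::xml_find_first(ont, "./rdfs:label", ns))
  m <- ontologyModel(iri, if (is.na(label)) "ontology" else label)
  for (imp in xml2::xml_find_all(ont, "./owl:imports", ns)) {
    im <- ontologyModel(xml2::xml_attr(imp, "resource"), "import")
    m@imports <- c(m@imports, list(im))
  }
  typeMap <- c("Class" = "class", "ObjectProperty" = "objectProperty",
               "DatatypeProperty" = "dataProperty",
               "NamedIndividual" = "individual")
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (!nm %in% names(typeMap)) next
    type <- typeMap[[nm]]
    lbl <- stripIRI(xml2::xml_attr(node, "about"))
    pref <- xml2::xml_text(xml2::xml_find_first(node, "./skos:prefLabel", ns))
    alts <- xml2::xml_text(xml2::xml_find_all(node, "./skos:altLabel", ns))
    m <- addEntity(m, lbl, type,
                   prefLabel = if (is.na(pref)) labelWords(lbl) else pref,
                   altLabels = alts)
    for (sub in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sub, "resource")
      if (!is.na(res)) {
        m <- addAxiom(m, "SubClassOf", lbl, object = stripIRI(res))
      } else {
        r <- xml2::xml_find_first(sub, "./owl:Restriction", ns)
        prop <- stripIRI(xml2::xml_attr(
          xml2::xml_find_first(r, "./owl:onProperty", ns), "resource"))
        qc <- xml2::xml_find_first(r, "./owl:qualifiedCardinality", ns)
        mqc <- xml2::xml_find_first(r, "./owl:maxQualifiedCardinality", ns)
        sv <- xml2::xml_find_first(r, "./owl:someValuesFrom", ns)
        onc <- xml2::xml_find_first(r, "./owl:onClass", ns)
        if (!inherits(qc, "xml_missing")) {
          m <- addAxiom(m, "ObjectExactCardinality", lbl, prop,
                        stripIRI(xml2::xml_attr(onc, "resource")),
                        as.integer(xml2::xml_text(qc)))
        } else if (!inherits(mqc, "xml_missing")) {
          m <- addAxiom(m, "ObjectMaxCardinality", lbl, prop,
                        stripIRI(xml2::xml_attr(onc, "resource")),
                        as.integer(xml2::xml_text(mqc)))
        } else if (!inherits(sv, "xml_missing")) {
          m <- addAxiom(m, "ObjectSomeValuesFrom", lbl, prop,
                        stripIRI(xml2::xml_attr(sv, "resource")))
        }
      }
    }
    for (spec in list(c("owl:disjointWith", "DisjointClasses"),
                      c("owl:inverseOf", "InverseObjectProperties"),
                      c("rdfs:subPropertyOf", "SubObjectPropertyOf"))) {
      for (x in xml2::xml_find_all(node, paste0("./", spec[1]), ns))
        m <- addAxiom(m, spec[2], lbl,
                      object = stripIRI(xml2::xml_attr(x, "resource")))
    }
    for (x in xml2::xml_find_all(node, "./rdfs:domain", ns))
      m <- addAxiom(m, if (type == "dataProperty") "DataPropertyDomain"
                       else "ObjectPropertyDomain",
                    lbl, object = stripIRI(xml2::xml_attr(x, "resource")))
    for (x in xml2::xml_find_all(node, "./rdfs:range", ns))
      m <- addAxiom(m, if (type == "dataProperty") "DataPropertyRange"
                       else "ObjectPropertyRange",
                    lbl, object = stripIRI(xml2::xml_attr(x, "resource")))
    for (x in xml2::xml_find_all(node, "./rdf:type", ns)) {
      if (grepl("FunctionalProperty", xml2::xml_attr(x, "resource")))
        m <- addAxiom(m, "FunctionalObjectProperty", lbl)
    }
  }
  m
}

# Turtle reader for the canonical subset emitted by exportTurtle (plus
# simple toys): prefix lines, one subject block per paragraph with
# ';'-separated predicate-object lines, '[...]' restriction values on a
# single line
importTurtle <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  base <- NA_character_
  for (ln in grep("^@prefix\\s+:", lines, value = TRUE))
    base <- sub("#>.*$", "", sub("^@prefix\\s+:\\s+<", "", ln))
  stmts <- character(0)   # accumulated full statements
  buf <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "@prefix") || startsWith(ln, "#"))
      next
    buf <- c(buf, ln)
    if (grepl("\\.\\s*$", ln)) {
      stmts <- c(stmts, paste(buf, collapse = " "))
      buf <- character(0)
    }
  }
  if (length(buf))
    dvStop(sprintf("Turtle parse failure near line %d: unterminated statement",
                   length(lines)), "parseError")
  m <- ontologyModel(if (is.na(base)) .dvBaseIRI else base, "ontology")
  unlit <- function(x) gsub('^"|"$', "", x)
  for (s in stmts) {
    s <- sub("\\s*\\.\\s*$", "", s)
    parts <- strsplit(s, "\\s*;\\s*(?![^\\[]*\\])", perl = TRUE)[[1]]
    head <- strsplit(parts[1], "\\s+")[[1]]
    subj <- head[1]
    preds <- c(paste(head[-1], collapse = " "), parts[-1])
    if (startsWith(subj, "<")) {           # the ontology header
      iri <- gsub("[<>]", "", subj)
      m@iri <- iri
      for (p in preds) {
        if (grepl("^rdfs:label", p))
          m@label <- unlit(sub("^rdfs:label\\s+", "", p))
        if (grepl("^owl:imports", p)) {
          im <- ontologyModel(gsub("[<>]", "",
                                   sub("^owl:imports\\s+", "", p)), "import")
          m@imports <- c(m@imports, list(im))
        }
      }
      next
    }
    lbl <- sub("^:", "", subj)
    typeLine <- grep("^(rdf:type|a)\\s", preds, value = TRUE)
    revMap <- c("owl:Class" = "class",
                "owl:ObjectProperty" = "objectProperty",
                "owl:DatatypeProperty" = "dataProperty",
                "owl:NamedIndividual" = "individual")
    type <- NA_character_
    for (tl in typeLine) {
      tv <- sub("^(rdf:type|a)\\s+", "", tl)
      if (tv %in% names(revMap)) type <- revMap[[tv]]
    }
    pref <- labelWords(lbl); alts <- character(0)
    for (p in preds) {
      if (grepl("^skos:prefLabel", p))
        pref <- unlit(sub("^skos:prefLabel\\s+", "", p))
      if (grepl("^skos:altLabel", p))
        alts <- c(alts, unlit(sub("^skos:altLabel\\s+", "", p)))
    }
    if (is.na(type)) {
      if (!lbl %in% m@entities$label) {
        # unrecognized fresh subject: preserve opaquely
        m <- addEntity(m, lbl, "individual", prefLabel = labelWords(lbl))
      }
      # an already-declared subject may receive further statements below
    } else {
      m <- addEntity(m, lbl, type, prefLabel = pref, altLabels = alts)
    }
    for (p in preds) {
      if (grepl("^rdfs:subClassOf\\s+:", p)) {
        m <- addAxiom(m, "SubClassOf", lbl,
                      object = sub("^rdfs:subClassOf\\s+:", "", p))
      } else if (grepl("^rdfs:subClassOf\\s+\\[", p)) {
        r <- p
        prop <- sub(".*owl:onProperty\\s+:([A-Za-z0-9]+).*", "\\1", r)
        if (grepl("owl:qualifiedCardinality", r)) {
          n <- as.integer(sub('.*owl:qualifiedCardinality\\s+"(\\d+)".*',
                              "\\1", r))
          obj <- sub(".*owl:onClass\\s+:([A-Za-z0-9]+).*", "\\1", r)
          m <- addAxiom(m, "ObjectExactCardinality", lbl, prop, obj, n)
        } else if (grepl("owl:maxQualifiedCardinality", r)) {
          n <- as.integer(sub(
            '.*owl:maxQualifiedCardinality\\s+"(\\d+)".*', "\\1", r))
          obj <- sub(".*owl:onClass\\s+:([A-Za-z0-9]+).*", "\\1", r)
          m <- addAxiom(m, "ObjectMaxCardinality", lbl, prop, obj, n)
        } else if (grepl("owl:someValuesFrom", r)) {
          obj <- sub(".*owl:someValuesFrom\\s+:([A-Za-z0-9]+).*", "\\1", r)
          m <- addAxiom(m, "ObjectSomeValuesFrom", lbl, prop, obj)
        }
      } else if (grepl("^owl:inverseOf\\s+:", p)) {
        m <- addAxiom(m, "InverseObjectProperties", lbl,
                      object = sub("^owl:inverseOf\\s+:", "", p))
      } else if (grepl("^rdfs:subPropertyOf\\s+:", p)) {
        m <- addAxiom(m, "SubObjectPropertyOf", lbl,
                      object = sub("^rdfs:subPropertyOf\\s+:", "", p))
      } else if (grepl("^owl:disjointWith\\s+:", p)) {
        m <- addAxiom(m, "DisjointClasses", lbl,
                      object = sub("^owl:disjointWith\\s+:", "", p))
      } else if (grepl("^rdfs:domain\\s+:", p)) {
        m <- addAxiom(m, if (type == "dataProperty") "DataPropertyDomain"
                         else "ObjectPropertyDomain",
                      lbl, object = sub("^rdfs:domain\\s+:", "", p))
      } else if (grepl("^rdfs:range\\s+xsd:", p)) {
        m <- addAxiom(m, "DataPropertyRange", lbl,
                      object = sub("^rdfs:range\\s+xsd:", "", p))
      } else if (grepl("^rdfs:range\\s+:", p)) {
        m <- addAxiom(m, "ObjectPropertyRange", lbl,
                      object = sub("^rdfs:range\\s+:", "", p))
      } else if (grepl("^rdf:type\\s+owl:FunctionalProperty", p)) {
        m <- addAxiom(m, "FunctionalObjectProperty", lbl)
      }
    }
  }
  m
}

## ---- structural consistency ----

#' Structural consistency check
#'
#' No description-logic reasoner is bundled; this performs the structural
#' checks a modeler wants before handing the file to an external reasoner:
#' conflicting exact cardinalities on the same class/property pair,
#' subclassing under two classes declared disjoint, and dangling axiom
#' references. The return value is a character vector of findings (empty
#' when clean), which also feeds the lawfulness score.
#'
#' @param model an [OntologyModel].
#' @return character vector of structural problems.
#' @export
structuralViolations <- function(model) {
  ax <- model@axioms
  probs <- character(0)
  card <- ax[ax$kind == "ObjectExactCardinality", , drop = FALSE]
  if (nrow(card)) {
    key <- paste(card$subject, card$property)
    for (k in unique(key[duplicated(key)])) {
      vals <- unique(card$value[key == k])
      if (length(vals) > 1)
        probs <- c(probs, sprintf(
          "conflicting exact cardinalities (%s) on %s",
          paste(vals, collapse = " vs "), k))
    }
  }
  dis <- ax[ax$kind == "DisjointClasses", , drop = FALSE]
  sub <- ax[ax$kind == "SubClassOf", , drop = FALSE]
  parents <- split(sub$object, sub$subject)
  for (cls in names(parents)) {
    ps <- parents[[cls]]
    for (j in seq_len(nrow(dis))) {
      if (dis$subject[j] %in% ps && dis$object[j] %in% ps)
        probs <- c(probs, sprintf(
          "%s is subsumed by disjoint classes %s and %s", cls,
          dis$subject[j], dis$object[j]))
    }
  }
  known <- model@entities$label
  for (im in model@imports) known <- c(known, im@entities$label)
  refd <- setdiff(stats::na.omit(c(ax$subject, ax$property,
                                   ax$object[!ax$kind %in%
                                               c("DataPropertyRange")])),
                  c(known, NA))
  if (length(refd))
    probs <- c(probs, sprintf("axiom references undeclared entity '%s'",
                              refd))
  probs
}
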