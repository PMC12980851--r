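---
title: "Methods: schema-driven construction of validated, de-identified patient knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: schema-driven construction of validated, de-identified patient knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Problem

Hospitals hold clinical data in heterogeneous source systems with
incompatible local representations. To make such data usable for research
across providers, it must be expressed against a shared semantic model,
checked against that model mechanically, and stripped of directly
identifying information — while remaining updatable (patients' records keep
changing) and deletable (patients may revoke consent). `healthkg`
implements this as a single schema-driven pipeline: everything the pipeline
does — input templates, structural validation, graph construction — is
derived from one machine-readable schema, so data providers and the
validation layer can never drift apart.

## The schema dialect

A schema is a Turtle document in a deliberately small description-logic
dialect:

* concepts are `owl:Class` declarations; exactly one carries
  `hkg:isSubject true` and denotes the patient;
* properties carry `rdfs:domain`/`rdfs:range`, with ranges drawn from XSD
  scalars and temporals, enumerated value sets (`hkg:ValueSet` with
  `hkg:member`), terminology-backed code sets (`hkg:ExternalValueSet`), or
  other concepts;
* cardinalities are `hkg:minCount`/`hkg:maxCount` (with `"unbounded"`);
* `hkg:eventStart`/`hkg:eventEnd` mark a concept's temporal interval pair;
* `hkg:sharedIdentifier true` marks cross-provider identifiers that must be
  emitted verbatim rather than minted into provider-scoped IRIs.

The parser rejects schemas violating the dialect's invariants (zero or
multiple subject classes, dangling domains/ranges, `minCount > maxCount`,
empty inline value sets). Inline value sets must enumerate their members;
terminology-backed sets are intentionally exempt, since their members live
in separately loaded terminology graphs.

**Core versus embedded concepts.** A concept is *core* when it is the
subject or reachable from the subject in one hop through a concept-ranged
property. Core concepts get their own tables in the tabular templates;
embedded concepts (e.g. an admission inside an administrative case) are
flattened into their owner's table with underscore-joined column prefixes
(`admission_admission_datetime`). This keeps the relational interchange
shallow while preserving nesting in the graph.

## Derived artifacts

From the parsed model the package derives, deterministically:

* a draft-07 **JSON Schema** (closed objects, enums for inline value sets,
  `date`/`date-time` formats, `$ref`-nested core and embedded concepts);
* **SQL DDL** (ANSI; `NOT NULL` from `minCount`, `CHECK ... IN` emulating
  enumerated types, composite primary keys on `(patient_id, id)`, side
  tables for multi-valued properties);
* **CSV header templates** mirroring the DDL;
* a **SHACL shapes graph** (`sh:minCount`, `sh:maxCount`, `sh:datatype`,
  `sh:nodeKind`, `sh:class`, `sh:in`, plus a `hkg:terminologyCheck`
  annotation resolved against the project's terminology graphs). The shapes
  graph embeds a 32-bit FNV-1a fingerprint of the model, and validation
  refuses shapes generated from a different schema version.

A coverage table records where each schema property landed, and the test
suite asserts that every property is covered exactly once by the templates
and exactly once by the shapes graph.

## Pipeline and zones

Each project is isolated under its own directory with Landing, Release and
Quarantine zones. A patient moves through:

1. **Input validation** — JSON documents against the derived JSON Schema,
   tabular deliveries against the derived templates (header equality,
   enumerated-type screening). Failures quarantine the patient with a
   machine-readable reason.
2. **Pre-check** — identifier well-formedness (`[A-Za-z0-9._~-]+`), inline
   value-set membership, temporal lexical forms. These are conditions that
   would corrupt minted IRIs or typed literals, so offenders are blocked
   *before* transformation.
3. **De-identification** (optional, see below).
4. **Transformation** — one named graph per patient. Instance IRIs follow a
   four-part convention `base/provider_uid/schema_prefix/Class/local_id`,
   which makes IRIs from different providers collision-free by
   construction. Shared identifiers bypass minting and stay plain literals.
5. **Validation** — the SHACL subset plus an interval logic check
   (`start > end` is a violation; `start == end` is allowed, and verdicts
   are invariant under date shifting since all of a patient's dates move by
   one constant). Non-conforming graphs still land in the Release zone,
   flagged by their report: validation is a quality signal, not a gate.

Because one patient is one named graph, a **delta load** replaces exactly
one graph and **consent revocation** deletes exactly one graph plus its
report; the test suite checks that any seeded sequence of deltas and
revocations leaves the store equal to a from-scratch rebuild of the final
state.

## De-identification model

Three mechanisms, all configured per project:

* **Field scrambling** replaces selected values (including instance
  identifiers) with version-4 UUIDs minted at random on first encounter —
  pseudonyms carry no information derived from the original. A persistent
  project log maps originals to pseudonyms so later deliveries replay
  byte-identically; links and the patient identifier are remapped
  coherently. A logging-free mode exists for one-off exports and refuses
  replay and persistence.
* **Date shifting** draws one uniform integer offset per patient from a
  configured day range and shifts the date part of every temporal value,
  preserving all pairwise intervals and the time of day. The offset is
  keyed by the *original* patient identifier, so replays are stable even
  when identifiers are also scrambled.
* **Substitutions** apply value-list or regex replacement rules to field
  values (e.g. redacting known name strings).

All randomness comes from a private RNG stream seeded by
`fnv1a32(project_salt, seed)`; the global RNG state is saved and restored
around every draw, so de-identification cannot perturb a caller's
simulations.

## Synthetic corpus and violation injection

`make_patients()` generates seeded corpora against the toy schema: one to
five administrative cases per patient (each with an embedded admission
whose discharge is at or after admission by construction), zero to ten
diagnoses coded from a twelve-code toy terminology and usually linked to a
case, up to two samples with optional shared identifiers, and always a sex
and usually birth date and name. The defaults are the study conditions used
by the acceptance properties; they were chosen to exercise every range
kind, cardinality class and link topology the dialect supports, not to make
any particular check pass.

With a positive `violation_rate`, `round(rate * n)` patients receive
exactly one mutation each from six kinds — `missing_mandatory`,
`bad_value_set`, `bad_datatype`, `start_after_end`, `malformed_id`,
`unknown_code` — and every applied mutation is recorded in a ledger. The
central recall property asserts that pipeline findings, matched on
(patient, kind) across both the quarantine and release layers, equal the
ledger exactly.

## Numerical and representational choices

* Quads are kept as canonical data frames with set semantics; graph
  equality is row-set equality after canonical ordering, which is exact
  (no floating-point comparisons — all literal values are carried as
  lexical forms).
* The package carries its own tokenizer/parser and serializers for the
  Turtle/TriG/N-Quads subset it emits, a SHACL-subset engine, and a
  JSON-Schema-subset evaluator, because the artifacts are controlled
  outputs of the package itself; an independent RDF stack (Python
  `rdflib`) is used in the test suite as a cross-check oracle for
  serialization.
* Temporal comparison converts date/date-time lexicals to seconds since
  epoch in UTC; malformed lexicals are routed to datatype findings rather
  than interval findings.
* The model fingerprint and seed derivation use 32-bit FNV-1a implemented
  in double arithmetic (R has no native unsigned 32-bit integers); the
  implementation is checked against published FNV test vectors.

## Limitations

* Validation is structural: schema-valid but clinically implausible values
  (a systolic pressure of 300) produce no findings by design. Plausibility
  rules would need a separate layer.
* The RDF layer covers only the subset of Turtle/TriG the package emits
  (no blank-node property lists in subject position, no language-tagged
  literal semantics beyond round-tripping, no relative IRI resolution).
* The SHACL engine implements the constraint components the generator can
  emit, not the full recommendation (no paths beyond single predicates, no
  logical constraint combinators).
* De-identification addresses direct identifiers and date linkage; it does
  not attempt k-anonymity or inference control, and shared identifiers are
  deliberately left linkable across providers.
* Date shifting preserves intervals exactly, which is a known
  re-identification trade-off accepted for research utility.
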