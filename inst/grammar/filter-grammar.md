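# Filter expression grammar

Boolean expressions over node or edge attributes, used by
`parse_filter()` / `evaluate_filter()` and the `--node-filter` /
`--edge-filter` CLI flags.

## Railroad-style reference

```
expr        ──▶ or_expr

or_expr     ──▶ and_expr ──┬────────────────────────▶
                           └─ "or" ── and_expr ──┐
                           ▲─────────────────────┘

and_expr    ──▶ not_expr ──┬────────────────────────▶
                           └─ "and" ── not_expr ──┐
                           ▲──────────────────────┘

not_expr    ──┬─ "not" ── not_expr ─▶
              └─ primary ───────────▶

primary     ──┬─ "(" ── expr ── ")" ─▶
              └─ comparison ─────────▶

comparison  ──▶ IDENT ── OP ── literal

OP          ──▶ "==" | "!=" | "<" | "<=" | ">" | ">="

literal     ──┬─ NUMBER ─▶          e.g.  10   0.2   -3.5e2
              └─ STRING ─▶          e.g.  'Tierralta'  "MDR-TB"

IDENT       ──▶ [A-Za-z_][A-Za-z0-9_.]*
```

## Semantics

- Precedence: `not` > `and` > `or`; parentheses override.
- Keywords `and`/`or`/`not` are case-insensitive; attribute names are
  case-sensitive.
- Ordering operators (`<`, `<=`, `>`, `>=`) require a numeric literal;
  using them with a quoted string is rejected at parse time.
- `==`/`!=` compare after kind unification: integers and floats compare
  numerically; a string never equals a number; string comparison is
  case-sensitive exact matching (no patterns).
- A comparison on an attribute the node/edge does not carry is `false`
  by default, so partially annotated data filters cleanly; strict mode
  turns this into an error instead.

## Examples

```
snp_distance <= 10
region == 'Tierralta'
probability >= 0.5 and not region == 'Other'
a == 'x' and (b > 2 or not c == 'y')
```
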