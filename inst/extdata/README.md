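# Bundled networks

Tiny, ubiquitously redistributed research datasets used as desk-scale test
beds for community detection. All files are plain text.

| file | network | nodes | edges | source |
|---|---|---|---|---|
| `karate.edges` | Zachary's karate club (1977), classic 1-based numbering | 34 | 78 | W. W. Zachary, *J. Anthropol. Res.* 33, 452-473 |
| `lesmis.edges` | Les Misérables character co-appearance | 77 | 254 | D. E. Knuth, *The Stanford GraphBase* (1993) |
| `football.gml` | American college football, Division I-A 2000 schedule | 115 | 613 unique (616 edge records; 3 duplicate pairs) | M. Girvan & M. E. J. Newman, *PNAS* 99, 7821-7826 (2002); original GML by M. Newman |

The dolphin social network (Lusseau, 62/159) and the political-books
co-purchase network (Krebs, 105/441) appear in the fixture catalog
(`ksim_fixtures()`) for reference but are not redistributed here; obtain a
local copy and load it with `read_graph()`.
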