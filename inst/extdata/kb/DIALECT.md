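# Knowledge-base XML dialect (AIML subset)

One file per dialogue context, UTF-8. Grammar:

```
aiml      := <aiml version="subset-1" language="es"> (topic | category)* </aiml>
topic     := <topic name=ID description=TEXT> category* </topic>
category  := <category [trigger="true"] [entry="true"] [fallback="true"]>
               <pattern> PATTERN </pattern>
               <template> BODY </template>
             </category>
PATTERN   := token sequence; tokens are normalized words, "*" or "_";
             each wildcard matches one or more input tokens
BODY      := ( TEXT | <get name=SLOT/> | <srai> PATTERN-TEXT </srai>
             | <random> <li>BODY</li>+ </random>
             | <condition name=SLOT>
                 <li value="present">BODY</li> [<li>BODY</li>]
               </condition> )*
SLOT      := schema slot name, or derived family slot
             fam<i>_name / parentesco_fam<i>
```

Semantics:

* Matching priority: `_` > exact token > `*`, resolved left to right;
  ties broken by authoring order. Search order: active context, then
  `trigger` categories of other contexts (switching context on match),
  then topic-less global categories.
* `entry` categories are rendered when the system itself opens the
  context (session start, or a system-proposed topic change).
* `fallback` categories use the reserved pattern `FALLBACK`; the dialogue
  manager renders them on no-match or when every template skips.
* A template referencing a slot the profile has not answered is skipped;
  `<condition>` branches on slot presence instead of skipping.
* `<srai>` re-matches its text in the same context (recursion depth 10).
* `<random>` selection is uniform, seeded, and avoids the most recent
  responses used in the context (non-repetition memory, default 3).

Authoring rules enforced by `lint_kb()`: outside `leave_conversation`
every rendered response ends with a question; every context offers at
least two response variants; sentences stay short.
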