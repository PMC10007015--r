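# Default assertion trigger set. Phrases are matched at the token level,
# case-insensitively, within a 6-token scope window.

[pre_negation]
no
without
negative for
no evidence of
absence of
free of
without evidence of
ruled out for

[post_negation]
is absent
are absent
not seen
not identified
not visualized
is excluded
has resolved

[pseudo_negation]
no significant interval change
no significant interval changes
no interval change
no interval changes
no significant change
no significant changes
no signs of rupture
no sign of rupture
no evidence of rupture
not significantly changed
no slightly increased size
no increase in size
no change in size

[terminators]
but
however
although
aside from
apart from
except
;
:
of the known
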