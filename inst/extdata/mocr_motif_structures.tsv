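n_boxes	category	regulogs	regulons
2	> >	70	186
2	< >	57	150
3	> > <	103	245
3	> < >	33	85
3	> > >	4	18
3	> < <	1	3
4	< < > >	8	39
4	> < > >	4	19
4	> > > <	3	14
4	> > < >	1	2
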